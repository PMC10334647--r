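#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   reverseComplement
NULL

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

read_fasta_chr <- function(path) {
  # Biostrings silently drops letters outside its DNA alphabet; surface
  # that as a parse error instead
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA parse error in '", path, "': ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA record '", names(seqs)[which(bad)[1L]],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  seqs
}

write_fasta_chr <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

new_contigset <- function(seq, coverage, style, partner = NULL) {
  ids <- names(seq)
  if (is.null(partner)) partner <- rep(NA_character_, length(ids))
  info <- data.frame(id = ids,
                     length = nchar(seq, type = "bytes"),
                     coverage = as.numeric(coverage),
                     style = style,
                     partner = partner,
                     stringsAsFactors = FALSE)
  rownames(info) <- NULL
  structure(list(seq = seq, info = info), class = "contigset")
}

#' @export
print.contigset <- function(x, ...) {
  cat(sprintf("contigset: %d contigs, %s bp total\n",
              nrow(x$info), format(sum(x$info$length), big.mark = ",")))
  print(table(x$info$style))
  invisible(x)
}

#' Read an input assembly in one of three haplotype styles
#'
#' Loads contigs from FASTA and annotates them with style tags, coverage and
#' (for paired-haplotype input) bubble partners.
#'
#' For \code{style = "paired_haplotype"} a sidecar TSV with columns
#' \code{contig_id}, \code{partner_id} (\code{"-"} for non-bubbles) and
#' \code{coverage} is required; within each bubble pair, the contig with more
#' non-N bases is tagged \code{primary_bubble} and its counterpart
#' \code{secondary_bubble}. For \code{style = "pseudo_haplotype"},
#' \code{fasta_path} holds the primary (pseudo-haplotype) sequences and
#' \code{alternative_fasta} the alternative sequences. For
#' \code{style = "haplotype_ignorant"} all contigs are tagged \code{plain}.
#'
#' @param fasta_path Path to the (primary) contig FASTA.
#' @param style One of \code{"paired_haplotype"}, \code{"pseudo_haplotype"},
#'   \code{"haplotype_ignorant"}.
#' @param pairing_sidecar Path to the pairing TSV (paired-haplotype only).
#' @param alternative_fasta Path to the alternative FASTA
#'   (pseudo-haplotype only).
#' @return A \code{contigset}: sequences plus a per-contig info table.
#' @export
read_assembly <- function(fasta_path, style, pairing_sidecar = NULL,
                          alternative_fasta = NULL) {
  style <- match.arg(style, c("paired_haplotype", "pseudo_haplotype",
                              "haplotype_ignorant"))
  seqs <- read_fasta_chr(fasta_path)
  if (style == "paired_haplotype") {
    if (is.null(pairing_sidecar))
      stop("paired_haplotype input requires a pairing sidecar TSV",
           call. = FALSE)
    sc <- utils::read.table(pairing_sidecar, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("contig_id", "partner_id", "coverage")
    if (!all(need %in% names(sc)))
      stop("pairing sidecar must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!all(names(seqs) %in% sc$contig_id))
      stop("sidecar is missing contigs: ",
           paste(setdiff(names(seqs), sc$contig_id)[1:3], collapse = ", "),
           call. = FALSE)
    sc <- sc[match(names(seqs), sc$contig_id), ]
    partner <- ifelse(sc$partner_id %in% c("-", ""), NA_character_,
                      sc$partner_id)
    bad <- !is.na(partner) & !(partner %in% names(seqs))
    if (any(bad))
      stop("sidecar partner not in FASTA: ", partner[which(bad)[1L]],
           call. = FALSE)
    nonN <- nchar(gsub("N", "", seqs, fixed = TRUE))
    style_tag <- rep("non_bubble", length(seqs))
    paired <- !is.na(partner)
    if (any(paired)) {
      p_nonN <- nonN[partner[paired]]
      primary <- nonN[paired] > p_nonN |
        (nonN[paired] == p_nonN & names(seqs)[paired] < partner[paired])
      style_tag[paired] <- ifelse(primary, "primary_bubble",
                                  "secondary_bubble")
    }
    return(new_contigset(seqs, sc$coverage, style_tag, partner))
  }
  if (style == "pseudo_haplotype") {
    if (is.null(alternative_fasta))
      stop("pseudo_haplotype input requires alternative_fasta", call. = FALSE)
    alt <- read_fasta_chr(alternative_fasta)
    if (any(names(alt) %in% names(seqs)))
      stop("duplicate ids between primary and alternative FASTA",
           call. = FALSE)
    all_seq <- c(seqs, alt)
    style_tag <- c(rep("pseudo_primary", length(seqs)),
                   rep("alternative", length(alt)))
    return(new_contigset(all_seq, rep(NA_real_, length(all_seq)), style_tag))
  }
  new_contigset(seqs, rep(NA_real_, length(seqs)),
                rep("plain", length(seqs)))
}

#' Convert Platanus-style FASTA headers to a pairing sidecar
#'
#' Recovers coverage from a \code{cov<number>} token in each id and bubble
#' pairing from matching \code{<stem>_p} / \code{<stem>_s} id suffixes, the
#' convention used by this package's simulator and by simple renamings of
#' Platanus-allee bubble output. Other ids become non-bubbles.
#'
#' @param fasta_path Contig FASTA whose ids carry the metadata.
#' @param out_tsv Output sidecar path.
#' @return Invisibly, the sidecar data frame.
#' @export
platanus_sidecar <- function(fasta_path, out_tsv) {
  seqs <- read_fasta_chr(fasta_path)
  ids <- names(seqs)
  cov <- suppressWarnings(as.numeric(sub(".*cov([0-9.]+).*", "\\1", ids)))
  cov[is.na(cov)] <- NA_real_
  core <- sub("_cov[0-9.]+", "", ids)
  stem <- sub("_[ps]$", "", core)
  suff <- ifelse(grepl("_p$", core), "p", ifelse(grepl("_s$", core), "s", ""))
  partner <- rep("-", length(ids))
  for (i in seq_along(ids)) {
    if (suff[i] == "") next
    j <- which(stem == stem[i] & suff == ifelse(suff[i] == "p", "s", "p"))
    if (length(j) == 1L) partner[i] <- ids[j]
  }
  df <- data.frame(contig_id = ids, partner_id = partner, coverage = cov,
                   stringsAsFactors = FALSE)
  utils::write.table(df, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

new_scafset <- function(members) {
  stopifnot(all(c("scaffold", "idx", "cons_id", "orient", "gap_after") %in%
                  names(members)))
  members <- members[order(members$scaffold, members$idx), ]
  rownames(members) <- NULL
  structure(list(members = members), class = "scafset")
}

singleton_scafset <- function(cons_ids) {
  new_scafset(data.frame(scaffold = paste0("scaffold_", seq_along(cons_ids)),
                         idx = 1L, cons_id = cons_ids, orient = "+",
                         gap_after = 0L, stringsAsFactors = FALSE))
}

#' @export
print.scafset <- function(x, ...) {
  n <- length(unique(x$members$scaffold))
  cat(sprintf("scafset: %d scaffolds, %d members\n", n, nrow(x$members)))
  invisible(x)
}

# Per-member placement: offset of each member in its scaffold (0-based),
# member length, scaffold length.
scaffold_placement <- function(scafset, seqlen) {
  m <- scafset$members
  len <- unname(seqlen[m$cons_id])
  if (anyNA(len))
    stop("scaffold member without sequence: ",
         m$cons_id[which(is.na(len))[1L]], call. = FALSE)
  off <- numeric(nrow(m))
  scaf_len <- numeric(0)
  for (s in unique(m$scaffold)) {
    i <- which(m$scaffold == s)
    step <- len[i] + m$gap_after[i]
    off[i] <- cumsum(c(0, step[-length(step)]))
    # trailing gap_after does not count towards scaffold length
    scaf_len[s] <- sum(len[i]) + sum(m$gap_after[i]) -
      m$gap_after[i][length(i)]
  }
  data.frame(scaffold = m$scaffold, cons_id = m$cons_id, orient = m$orient,
             offset = off, len = len,
             scaf_len = unname(scaf_len[m$scaffold]),
             stringsAsFactors = FALSE)
}

scaffold_lengths <- function(scafset, seqlen) {
  pl <- scaffold_placement(scafset, seqlen)
  sl <- pl[!duplicated(pl$scaffold), c("scaffold", "scaf_len")]
  stats::setNames(sl$scaf_len, sl$scaffold)
}

scaffold_sequences <- function(scafset, seqs) {
  m <- scafset$members
  out <- character(0)
  for (s in unique(m$scaffold)) {
    i <- which(m$scaffold == s)
    parts <- character(0)
    for (k in seq_along(i)) {
      row <- i[k]
      sq <- seqs[[m$cons_id[row]]]
      if (m$orient[row] == "-") sq <- revcomp(sq)
      parts <- c(parts, sq)
      if (k < length(i) && m$gap_after[row] > 0)
        parts <- c(parts, strrep("N", m$gap_after[row]))
    }
    out[s] <- paste(parts, collapse = "")
  }
  out
}

#' Write scaffolds as FASTA and AGP v2.1
#'
#' Emits scaffold sequences (members joined by runs of \code{N}, minus-strand
#' members reverse-complemented) and the matching AGP v2.1 placement, with
#' 1-based inclusive coordinates.
#'
#' @param scafset Scaffold set (as produced by the scaffolding stage).
#' @param seqs Named character vector of member (consensus contig) sequences.
#' @param out_fasta,out_agp Output paths.
#' @return Invisibly, the named vector of scaffold lengths.
#' @export
write_scaffolds <- function(scafset, seqs, out_fasta, out_agp) {
  m <- scafset$members
  missing <- setdiff(m$cons_id, names(seqs))
  if (length(missing))
    stop("scaffold member without sequence: ", missing[1L], call. = FALSE)
  fa <- scaffold_sequences(scafset, seqs)
  write_fasta_chr(fa, out_fasta)
  rows <- list()
  for (s in unique(m$scaffold)) {
    i <- which(m$scaffold == s)
    pos <- 0L
    part <- 0L
    for (k in seq_along(i)) {
      row <- i[k]
      len <- nchar(seqs[[m$cons_id[row]]])
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = s, object_beg = pos + 1L, object_end = pos + len,
        part_number = part, component_type = "W",
        f1 = m$cons_id[row], f2 = 1L, f3 = len, f4 = m$orient[row],
        stringsAsFactors = FALSE)
      pos <- pos + len
      gap <- m$gap_after[row]
      if (k < length(i) && gap > 0) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = s, object_beg = pos + 1L, object_end = pos + gap,
          part_number = part, component_type = "N",
          f1 = as.character(gap), f2 = "scaffold", f3 = "yes",
          f4 = "proximity_ligation", stringsAsFactors = FALSE)
        pos <- pos + gap
      }
    }
  }
  con <- file(out_agp, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (length(rows)) {
    agp <- do.call(rbind, rows)
    utils::write.table(agp, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(stats::setNames(nchar(fa), names(fa)))
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns; optional SAM-style tags are ignored.
#'
#' @param path PAF file path.
#' @return Data frame with columns \code{qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alen, mapq} (coordinates 0-based
#'   half-open, as in PAF).
#' @export
read_paf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(qname = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), tname = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), nmatch = integer(0),
                      alen = integer(0), mapq = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed PAF line ", which(nf < 12L)[1L], ": fewer than 12 fields",
         call. = FALSE)
  g <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(g(i)))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1L],
           ": non-numeric field ", i, call. = FALSE)
    v
  }
  data.frame(qname = g(1), qlen = num(2), qstart = num(3), qend = num(4),
             strand = g(5), tname = g(6), tlen = num(7), tstart = num(8),
             tend = num(9), nmatch = num(10), alen = num(11), mapq = num(12),
             stringsAsFactors = FALSE)
}

#' @param paf A PAF data frame (the 12 mandatory columns).
#' @rdname read_paf
#' @export
write_paf <- function(paf, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  utils::write.table(paf[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write Hi-C "pairs"-style contact tables
#'
#' Tab-separated records \code{read_id, seq_a, pos_a, seq_b, pos_b} with
#' 0-based positions; header lines starting with \code{#} are skipped.
#'
#' @param path File path.
#' @return Data frame with columns \code{read_id, seq_a, pos_a, seq_b, pos_b}.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("read_id", "seq_a", "pos_a",
                                        "seq_b", "pos_b"))
  df$pos_a <- as.numeric(df$pos_a)
  df$pos_b <- as.numeric(df$pos_b)
  df
}

#' @param pairs Data frame as returned by [read_pairs()].
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("read_id", "seq_a", "pos_a", "seq_b", "pos_b")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
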