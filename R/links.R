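# Typed link evidence from read alignments: unique k-mer short-read
# mapping (with consensus links), greedy identity-ordered long-read
# alignment selection, Hi-C contact collection, and lifting of
# member-contig coordinates onto consensus contigs.

all_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Map short reads to contigs by unique k-mer exact match
#'
#' A read maps where one of its k-mers matches a single contig. A k-mer
#' matching exactly two contigs that are the two members of one consensus
#' contig maps the read to the primary member with \code{kind =
#' "consensus"}; k-mers matching more than two contigs, or two unrelated
#' ones, are discarded. The first (leftmost) mapping k-mer of each read
#' decides. Consensus-kind records are used in consensus scaffolding but
#' must never be used in phasing.
#'
#' @param reads Named character vector of read sequences.
#' @param contigs Named character vector of contig sequences (members).
#' @param cons Optional \code{consensus_set} enabling consensus links.
#' @param k k-mer size.
#' @return Data frame \code{read_id, ctg, pos, kind} (0-based mapped
#'   position of the read start; \code{kind} is \code{"unique"} or
#'   \code{"consensus"}). Unmapped reads are absent.
#' @export
map_short_reads <- function(reads, contigs, cons = NULL, k = 32L) {
  if (any(nchar(reads) < k)) stop("k exceeds a read length", call. = FALSE)
  dict_km <- character(0); dict_ctg <- character(0); dict_pos <- integer(0)
  for (cn in names(contigs)) {
    km <- all_kmers(contigs[[cn]], k)
    dict_km <- c(dict_km, km)
    dict_ctg <- c(dict_ctg, rep(cn, length(km)))
    dict_pos <- c(dict_pos, seq_along(km) - 1L)
  }
  # contigs hit by each distinct k-mer
  hit_ctgs <- tapply(dict_ctg, dict_km, unique)
  # one representative position per (k-mer, contig)
  first_idx <- !duplicated(paste(dict_km, dict_ctg, sep = "\r"))
  pos_lookup <- stats::setNames(
    dict_pos[first_idx], paste(dict_km[first_idx], dict_ctg[first_idx],
                               sep = "\r"))
  pair_of <- if (!is.null(cons)) {
    mm <- cons$member_map
    stats::setNames(mm$cons_id, mm$member)
  } else NULL
  primary_of <- if (!is.null(cons)) {
    mm <- cons$member_map
    stats::setNames(mm$member[mm$slot == 0L], mm$cons_id[mm$slot == 0L])
  } else NULL
  out <- list()
  for (rn in names(reads)) {
    kms <- all_kmers(reads[[rn]], k)
    hits <- hit_ctgs[kms]
    for (i in seq_along(kms)) {
      h <- hits[[i]]
      if (is.null(h) || anyNA(h)) next
      # count of occurrences of this k-mer across the whole contig set
      n_occ <- sum(dict_km == kms[i])
      if (length(h) == 1L && n_occ == 1L) {
        p <- pos_lookup[[paste(kms[i], h, sep = "\r")]]
        out[[length(out) + 1L]] <- data.frame(
          read_id = rn, ctg = h, pos = p - (i - 1L), kind = "unique",
          stringsAsFactors = FALSE)
        break
      }
      if (length(h) == 2L && n_occ == 2L && !is.null(pair_of)) {
        ca <- pair_of[h[1L]]; cb <- pair_of[h[2L]]
        if (!is.na(ca) && !is.na(cb) && ca == cb) {
          tgt <- primary_of[[ca]]
          if (!(tgt %in% h)) tgt <- h[1L]
          p <- pos_lookup[[paste(kms[i], tgt, sep = "\r")]]
          out[[length(out) + 1L]] <- data.frame(
            read_id = rn, ctg = tgt, pos = p - (i - 1L),
            kind = "consensus", stringsAsFactors = FALSE)
          break
        }
      }
      # ambiguous: try the next k-mer
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(0), ctg = character(0),
                      pos = integer(0), kind = character(0)))
  do.call(rbind, out)
}

#' Join mapped mates into paired link records
#'
#' Mates are matched by a shared read id with \code{/1} / \code{/2}
#' suffixes; each fully mapped pair yields one link record joining the two
#' mapped positions. A pair is tagged \code{kind = "consensus"} when either
#' mate mapped through a consensus k-mer.
#'
#' @param mapped Output of [map_short_reads()].
#' @return Data frame \code{read_id, ctg_a, pos_a, ctg_b, pos_b, kind}.
#' @export
pair_mapped_reads <- function(mapped) {
  stem <- sub("/[12]$", "", mapped$read_id)
  mate <- sub("^.*/", "", mapped$read_id)
  m1 <- mapped[mate == "1", , drop = FALSE]
  m2 <- mapped[mate == "2", , drop = FALSE]
  s1 <- sub("/[12]$", "", m1$read_id)
  s2 <- sub("/[12]$", "", m2$read_id)
  idx <- match(s1, s2)
  ok <- !is.na(idx)
  data.frame(read_id = s1[ok],
             ctg_a = m1$ctg[ok], pos_a = m1$pos[ok],
             ctg_b = m2$ctg[idx[ok]], pos_b = m2$pos[idx[ok]],
             kind = ifelse(m1$kind[ok] == "consensus" |
                             m2$kind[idx[ok]] == "consensus",
                           "consensus", "paired_end"),
             stringsAsFactors = FALSE)
}

#' Greedy identity-ordered selection of long-read alignments
#'
#' Per read, alignments are accepted in decreasing sequence identity
#' (\code{nmatch / alen}; ties broken by longer alignment, then target id,
#' then read start), skipping any alignment whose read interval overlaps an
#' already accepted one. Alignments shorter than
#' \code{min_longread_alignment} are dropped first.
#'
#' @param paf PAF data frame (from [read_paf()] or [truth_paf()]).
#' @param config A \code{hapscaf_config}.
#' @return The accepted subset of \code{paf} with an \code{identity}
#'   column, ordered by read and read-start.
#' @export
select_long_read_alignments <- function(paf, config = scaffold_config()) {
  paf <- paf[paf$alen >= config$min_longread_alignment, , drop = FALSE]
  if (!nrow(paf)) { paf$identity <- numeric(0); return(paf) }
  paf$identity <- paf$nmatch / paf$alen
  keep <- logical(nrow(paf))
  ord <- order(paf$qname, -paf$identity, -paf$alen, paf$tname, paf$qstart)
  paf_o <- paf[ord, ]
  cur_read <- ""
  acc_s <- numeric(0); acc_e <- numeric(0)
  for (i in seq_len(nrow(paf_o))) {
    if (paf_o$qname[i] != cur_read) {
      cur_read <- paf_o$qname[i]
      acc_s <- numeric(0); acc_e <- numeric(0)
    }
    if (!any(paf_o$qstart[i] < acc_e & paf_o$qend[i] > acc_s)) {
      keep[ord[i]] <- TRUE
      acc_s <- c(acc_s, paf_o$qstart[i])
      acc_e <- c(acc_e, paf_o$qend[i])
    }
  }
  res <- paf[keep, , drop = FALSE]
  res[order(res$qname, res$qstart), , drop = FALSE]
}

#' Long-read links between contigs from selected alignments
#'
#' Consecutive accepted alignments of one read to different contigs yield a
#' link joining the facing contig ends, with the read-interval distance as
#' the estimated gap.
#'
#' @param selected Output of [select_long_read_alignments()].
#' @return Data frame \code{read_id, ctg_a, end_a, pos_a, ctg_b, end_b,
#'   pos_b, gap} with ends \code{"5p"}/\code{"3p"}.
#' @export
longread_links <- function(selected) {
  empty <- data.frame(read_id = character(0), ctg_a = character(0),
                      end_a = character(0), pos_a = numeric(0),
                      ctg_b = character(0), end_b = character(0),
                      pos_b = numeric(0), gap = numeric(0))
  if (!nrow(selected)) return(empty)
  sel <- selected[order(selected$qname, selected$qstart), ]
  out <- list()
  n <- nrow(sel)
  same_read <- sel$qname[-1L] == sel$qname[-n]
  for (i in which(same_read)) {
    a <- i; b <- i + 1L
    if (sel$tname[a] == sel$tname[b]) next
    end_a <- if (sel$strand[a] == "+") "3p" else "5p"
    pos_a <- if (sel$strand[a] == "+") sel$tend[a] - 1 else sel$tstart[a]
    end_b <- if (sel$strand[b] == "+") "5p" else "3p"
    pos_b <- if (sel$strand[b] == "+") sel$tstart[b] else sel$tend[b] - 1
    out[[length(out) + 1L]] <- data.frame(
      read_id = sel$qname[a], ctg_a = sel$tname[a], end_a = end_a,
      pos_a = pos_a, ctg_b = sel$tname[b], end_b = end_b, pos_b = pos_b,
      gap = max(sel$qstart[b] - sel$qend[a], 0),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Collect Hi-C contacts from a mapped-pairs table
#'
#' Validates that both ends reference known sequences and returns the
#' unordered contact records (insert length and orientation are ignored by
#' design).
#'
#' @param pairs Data frame from [read_pairs()] (or [contacts_to_pairs()]).
#' @param seq_lengths Named lengths of the valid sequence set.
#' @return Data frame \code{seq_a, pos_a, seq_b, pos_b}.
#' @export
collect_hic_contacts <- function(pairs, seq_lengths) {
  bad <- setdiff(unique(c(pairs$seq_a, pairs$seq_b)), names(seq_lengths))
  if (length(bad))
    stop("contact references unknown sequence: ", bad[1L], call. = FALSE)
  if (any(pairs$pos_a >= seq_lengths[pairs$seq_a] |
          pairs$pos_b >= seq_lengths[pairs$seq_b] |
          pairs$pos_a < 0 | pairs$pos_b < 0))
    stop("contact position outside its sequence", call. = FALSE)
  pairs[, c("seq_a", "pos_a", "seq_b", "pos_b")]
}

#' Lift member-contig contacts onto consensus contigs
#'
#' @param contacts Member-level contacts (\code{seq_a, pos_a, seq_b,
#'   pos_b}).
#' @param cons A \code{consensus_set}.
#' @return Contacts re-expressed against consensus contig ids/coordinates.
#' @export
contacts_to_consensus <- function(contacts, cons) {
  a <- member_to_consensus(contacts$seq_a, contacts$pos_a, cons)
  b <- member_to_consensus(contacts$seq_b, contacts$pos_b, cons)
  data.frame(seq_a = a$cons_id, pos_a = a$pos,
             seq_b = b$cons_id, pos_b = b$pos,
             stringsAsFactors = FALSE)
}

# Aggregate member-level long-read links into consensus end-edges:
# (cons_a, end_a, cons_b, end_b, n, gap). Intra-consensus links are
# dropped (they join the two members of one locus). Secondary members are
# assumed co-oriented with their primary.
links_to_consensus_edges <- function(links, cons) {
  if (!nrow(links))
    return(data.frame(id_a = character(0), end_a = character(0),
                      id_b = character(0), end_b = character(0),
                      n = integer(0), gap = numeric(0)))
  mm <- cons$member_map
  cons_of <- stats::setNames(mm$cons_id, mm$member)
  ca <- cons_of[links$ctg_a]; cb <- cons_of[links$ctg_b]
  ok <- !is.na(ca) & !is.na(cb) & ca != cb
  links <- links[ok, , drop = FALSE]
  ca <- ca[ok]; cb <- cb[ok]
  if (!nrow(links))
    return(links_to_consensus_edges(links[0, ], cons))
  # canonical orientation of each edge record
  flip <- ca > cb
  id_a <- ifelse(flip, cb, ca); id_b <- ifelse(flip, ca, cb)
  end_a <- ifelse(flip, links$end_b, links$end_a)
  end_b <- ifelse(flip, links$end_a, links$end_b)
  key <- paste(id_a, end_a, id_b, end_b, sep = "\r")
  n <- as.integer(table(key))
  gap <- tapply(links$gap, key, stats::median)
  parts <- do.call(rbind, strsplit(names(gap), "\r", fixed = TRUE))
  data.frame(id_a = parts[, 1L], end_a = parts[, 2L],
             id_b = parts[, 3L], end_b = parts[, 4L],
             n = as.integer(table(key)[names(gap)]),
             gap = as.numeric(gap), stringsAsFactors = FALSE)
}

# Per-consensus-contig long-read coverage from selected alignments
# (member alignments lifted onto the consensus sequence).
consensus_coverage <- function(selected, cons) {
  covs <- lapply(cons$T$id, function(id)
    numeric(nchar(cons$seq[[id]])))
  names(covs) <- cons$T$id
  if (!nrow(selected)) return(covs)
  s <- member_to_consensus(selected$tname, selected$tstart, cons)
  e <- member_to_consensus(selected$tname, pmax(selected$tend - 1, 0), cons)
  for (i in seq_len(nrow(selected))) {
    id <- s$cons_id[i]
    lo <- min(s$pos[i], e$pos[i]) + 1L
    hi <- max(s$pos[i], e$pos[i]) + 1L
    covs[[id]][lo:hi] <- covs[[id]][lo:hi] + 1
  }
  covs
}
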