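# Haplotig merging: convert any input style to paired-haplotype form and
# merge homologous pairs into consensus contigs (array T).

#' All-vs-all self-alignment of contigs
#'
#' Runs minimap2 (options \code{-D --secondary=no}) on the contig set
#' against itself and keeps alignments with identity
#' (\code{nmatch / alen}) at or above \code{identity_min}. Self-hits are
#' excluded.
#'
#' @param contigs A \code{contigset}.
#' @param config A \code{hapscaf_config}.
#' @param paf Optional precomputed PAF data frame (as from [read_paf()]);
#'   when supplied minimap2 is not run.
#' @return Alignment data frame with an added \code{identity} column.
#' @export
self_align_contigs <- function(contigs, config = scaffold_config(),
                               paf = NULL) {
  if (nrow(contigs$info) < 1L) stop("empty contig set", call. = FALSE)
  if (is.null(paf)) {
    mm2 <- Sys.which("minimap2")
    if (mm2 == "")
      stop("minimap2 not found on PATH; supply alignments via `paf`",
           call. = FALSE)
    fa <- tempfile(fileext = ".fa")
    out <- tempfile(fileext = ".paf")
    on.exit(unlink(c(fa, out)), add = TRUE)
    write_fasta_chr(contigs$seq, fa)
    status <- system2(mm2, c("-D", "--secondary=no", "-o", out, fa, fa),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("minimap2 failed (exit ", status, ")",
                          call. = FALSE)
    paf <- read_paf(out)
  }
  paf <- paf[paf$qname != paf$tname, , drop = FALSE]
  paf$identity <- ifelse(paf$alen > 0, paf$nmatch / paf$alen, 0)
  paf[paf$identity >= config$identity_min, , drop = FALSE]
}

#' Assign an opposite contig to each contig
#'
#' Per contig, candidate opposite = the contig with the longest total
#' retained alignment. Candidates are committed greedily in decreasing
#' alignment length; a contig whose claim on its opposite overlaps a claim
#' already committed by a different contig is removed as a repeat.
#' Alignments shorter than \code{min_opposite_alignment} cannot create an
#' assignment.
#'
#' @param contigs A \code{contigset}.
#' @param alignments Output of [self_align_contigs()].
#' @param config A \code{hapscaf_config}.
#' @return List: \code{assoc} (contig, opposite, intervals on both,
#'   strand, alen), \code{removed} (repeat contig ids), \code{unpaired}
#'   (ids with no assignment).
#' @export
assign_opposites <- function(contigs, alignments,
                             config = scaffold_config()) {
  ids <- contigs$info$id
  al <- alignments[alignments$alen >= config$min_opposite_alignment, ,
                   drop = FALSE]
  cand <- NULL
  if (nrow(al)) {
    # aggregate per ordered (query, target) pair
    key <- paste(al$qname, al$tname, sep = "\r")
    agg_len <- tapply(al$alen, key, sum)
    qs <- tapply(al$qstart, key, min); qe <- tapply(al$qend, key, max)
    ts <- tapply(al$tstart, key, min); te <- tapply(al$tend, key, max)
    strand <- tapply(al$strand, key, function(s)
      names(sort(table(s), decreasing = TRUE))[1L])
    pk <- do.call(rbind, strsplit(names(agg_len), "\r", fixed = TRUE))
    pairs <- data.frame(contig = pk[, 1L], opposite = pk[, 2L],
                        c_start = as.numeric(qs), c_end = as.numeric(qe),
                        o_start = as.numeric(ts), o_end = as.numeric(te),
                        strand = as.character(strand),
                        alen = as.numeric(agg_len),
                        stringsAsFactors = FALSE)
    # per contig keep the longest-aligned opposite
    pairs <- pairs[order(-pairs$alen, pairs$contig, pairs$opposite), ]
    cand <- pairs[!duplicated(pairs$contig), , drop = FALSE]
    cand <- cand[order(-cand$alen, cand$contig), , drop = FALSE]
  }
  assoc <- list()
  removed <- character(0)
  claims <- list()  # per contig: data.frame(start, end, partner)
  add_claim <- function(ctg, start, end, partner) {
    df <- claims[[ctg]]
    row <- data.frame(start = start, end = end, partner = partner,
                      stringsAsFactors = FALSE)
    claims[[ctg]] <<- if (is.null(df)) row else rbind(df, row)
  }
  if (!is.null(cand)) for (i in seq_len(nrow(cand))) {
    u <- cand$contig[i]; o <- cand$opposite[i]
    if (u %in% removed || o %in% removed) next
    cl <- claims[[o]]
    if (!is.null(cl)) {
      ov <- cl$start < cand$o_end[i] & cl$end > cand$o_start[i]
      if (any(ov)) {
        if (any(cl$partner[ov] == u)) next  # mutual confirmation
        removed <- c(removed, u)
        next
      }
    }
    assoc[[length(assoc) + 1L]] <- cand[i, , drop = FALSE]
    add_claim(o, cand$o_start[i], cand$o_end[i], u)
    add_claim(u, cand$c_start[i], cand$c_end[i], o)
  }
  assoc <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(contig = character(0), opposite = character(0),
               c_start = numeric(0), c_end = numeric(0),
               o_start = numeric(0), o_end = numeric(0),
               strand = character(0), alen = numeric(0),
               stringsAsFactors = FALSE)
  rownames(assoc) <- NULL
  paired <- union(assoc$contig, assoc$opposite)
  list(assoc = assoc, removed = removed, claims = claims,
       unpaired = setdiff(ids, c(paired, removed)))
}

# merge short slivers into their neighbours and return cut positions
clean_boundaries <- function(bounds, len, min_piece) {
  b <- sort(unique(pmin(pmax(bounds, 0), len)))
  b <- b[b > 0 & b < len]
  keep <- logical(length(b))
  prev <- 0
  for (i in seq_along(b)) {
    if (b[i] - prev >= min_piece && len - b[i] >= min_piece) {
      keep[i] <- TRUE
      prev <- b[i]
    }
  }
  b[keep]
}

#' Mince contigs at association boundaries and tag pieces
#'
#' Cuts each non-removed contig at the boundaries of its association
#' intervals so every piece is either fully associated with one opposite
#' piece or unassociated; associated pieces receive coverage
#' \code{C_consensus}, unassociated pieces \code{2 * C_consensus}.
#' Associated piece pairs become bubble pairs (the piece with more non-N
#' bases is primary). Pieces shorter than \code{min_piece} are merged into
#' a neighbour.
#'
#' @param contigs A \code{contigset}.
#' @param assignments Output of [assign_opposites()].
#' @param config A \code{hapscaf_config}.
#' @return List: \code{contigs} (paired-haplotype style \code{contigset}),
#'   \code{provenance} (piece, source, offset, length).
#' @export
mince_and_tag <- function(contigs, assignments,
                          config = scaffold_config()) {
  C <- config$C_consensus
  ids <- setdiff(contigs$info$id, assignments$removed)
  pieces <- list()     # per source contig: data.frame(piece, start, end)
  prov <- list()
  piece_seq <- character(0)
  piece_cov <- numeric(0)
  for (u in ids) {
    len <- nchar(contigs$seq[[u]])
    cl <- assignments$claims[[u]]
    bounds <- if (is.null(cl)) numeric(0) else c(cl$start, cl$end)
    cuts <- clean_boundaries(bounds, len, config$min_piece)
    starts <- c(0, cuts); ends <- c(cuts, len)
    pid <- if (length(starts) == 1L) u else
      sprintf("%s.%d", u, seq_along(starts))
    for (k in seq_along(starts)) {
      piece_seq[pid[k]] <- substr(contigs$seq[[u]], starts[k] + 1L, ends[k])
      mid <- (starts[k] + ends[k]) / 2
      associated <- !is.null(cl) && any(cl$start <= mid & cl$end > mid)
      piece_cov[pid[k]] <- if (associated) C else 2 * C
      prov[[length(prov) + 1L]] <- data.frame(
        piece = pid[k], source = u, offset = starts[k],
        length = ends[k] - starts[k], stringsAsFactors = FALSE)
    }
    pieces[[u]] <- data.frame(piece = pid, start = starts, end = ends,
                              stringsAsFactors = FALSE)
  }
  # pair pieces through the association intervals
  partner <- stats::setNames(rep(NA_character_, length(piece_seq)),
                             names(piece_seq))
  assoc <- assignments$assoc
  sel_pieces <- function(u, lo, hi) {
    p <- pieces[[u]]
    p$piece[(p$start + p$end) / 2 >= lo & (p$start + p$end) / 2 < hi]
  }
  if (nrow(assoc)) for (i in seq_len(nrow(assoc))) {
    u <- assoc$contig[i]; o <- assoc$opposite[i]
    pu <- sel_pieces(u, assoc$c_start[i], assoc$c_end[i])
    po <- sel_pieces(o, assoc$o_start[i], assoc$o_end[i])
    if (assoc$strand[i] == "-") po <- rev(po)
    n <- min(length(pu), length(po))
    if (n == 0L) next
    for (k in seq_len(n)) {
      if (is.na(partner[pu[k]]) && is.na(partner[po[k]])) {
        partner[pu[k]] <- po[k]
        partner[po[k]] <- pu[k]
      }
    }
  }
  nonN <- nchar(gsub("N", "", piece_seq, fixed = TRUE))
  style <- character(length(piece_seq))
  names(style) <- names(piece_seq)
  for (p in names(piece_seq)) {
    if (is.na(partner[p])) { style[p] <- "non_bubble"; next }
    q <- partner[p]
    style[p] <- if (nonN[p] > nonN[q] ||
                    (nonN[p] == nonN[q] && p < q)) "primary_bubble"
    else "secondary_bubble"
  }
  cs <- new_contigset(piece_seq, piece_cov, unname(style[names(piece_seq)]),
                      unname(partner[names(piece_seq)]))
  list(contigs = cs, provenance = do.call(rbind, prov))
}

#' Classify a non-bubble contig from its coverage
#'
#' Heterozygous iff \code{coverage < C_hetero * r_upper_threshold}
#' (strict).
#'
#' @param coverage Contig coverage (depth).
#' @param C_hetero Mean coverage of heterozygous (bubble) contigs.
#' @param r_upper_threshold Multiplier (default 1.75).
#' @return \code{"heterozygous_unpaired"} or \code{"homozygous"}.
#' @export
classify_nonbubble <- function(coverage, C_hetero,
                               r_upper_threshold = 1.75) {
  if (!is.finite(C_hetero) || C_hetero <= 0)
    stop("C_hetero must be positive", call. = FALSE)
  ifelse(coverage < C_hetero * r_upper_threshold,
         "heterozygous_unpaired", "homozygous")
}

estimate_c_hetero <- function(contigs, config) {
  bub <- contigs$info$coverage[contigs$info$style %in%
                                 c("primary_bubble", "secondary_bubble")]
  bub <- bub[is.finite(bub)]
  if (length(bub)) return(mean(bub))
  cov <- contigs$info$coverage[is.finite(contigs$info$coverage)]
  if (length(cov) >= 2L) {
    d <- stats::density(cov)
    return(d$x[which.max(d$y)] / 2)  # half the main coverage peak
  }
  config$C_consensus
}

#' Merge paired-haplotype contigs into consensus contigs (array T)
#'
#' Each primary/secondary bubble pair \code{(u, v)} becomes one consensus
#' contig with entry \code{[u, v]} whose sequence is the primary member's;
#' non-bubble contigs become \code{[u, -]} (heterozygous by the coverage
#' rule) or \code{[u, u]} (homozygous).
#'
#' @param contigs A paired-haplotype style \code{contigset}.
#' @param config A \code{hapscaf_config}.
#' @return A \code{"consensus_set"}: \code{seq} (consensus sequences),
#'   \code{T} (id, member0, member1, class), \code{member_map} (member,
#'   cons_id, slot, length).
#' @export
build_consensus <- function(contigs, config = scaffold_config()) {
  info <- contigs$info
  if (!nrow(info))
    return(structure(list(seq = character(0),
                          T = data.frame(id = character(0),
                                         member0 = character(0),
                                         member1 = character(0),
                                         class = character(0)),
                          member_map = data.frame(member = character(0),
                                                  cons_id = character(0),
                                                  slot = integer(0),
                                                  length = integer(0))),
                     class = "consensus_set"))
  C_het <- estimate_c_hetero(contigs, config)
  rows <- list(); seqs <- character(0); mmap <- list()
  used <- character(0)
  cid <- 0L
  next_id <- function() { cid <<- cid + 1L; sprintf("cc%04d", cid) }
  prim <- info[info$style == "primary_bubble", , drop = FALSE]
  for (i in seq_len(nrow(prim))) {
    u <- prim$id[i]; v <- prim$partner[i]
    if (is.na(v)) stop("primary bubble without partner: ", u, call. = FALSE)
    if (v %in% used || u %in% used)
      stop("bubble partner referenced twice: ", v, call. = FALSE)
    id <- next_id()
    rows[[id]] <- data.frame(id = id, member0 = u, member1 = v,
                             class = "het_paired", stringsAsFactors = FALSE)
    seqs[id] <- contigs$seq[[u]]
    mmap[[length(mmap) + 1L]] <- data.frame(
      member = c(u, v), cons_id = id, slot = c(0L, 1L),
      length = c(nchar(contigs$seq[[u]]), nchar(contigs$seq[[v]])),
      stringsAsFactors = FALSE)
    used <- c(used, u, v)
  }
  rest <- info[!(info$id %in% used) & info$style != "secondary_bubble", ,
               drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    u <- rest$id[i]
    cls <- if (is.finite(rest$coverage[i]))
      classify_nonbubble(rest$coverage[i], C_het, config$r_upper_threshold)
    else "heterozygous_unpaired"
    id <- next_id()
    rows[[id]] <- data.frame(
      id = id, member0 = u,
      member1 = if (cls == "homozygous") u else "-",
      class = if (cls == "homozygous") "homo" else "het_unpaired",
      stringsAsFactors = FALSE)
    seqs[id] <- contigs$seq[[u]]
    mmap[[length(mmap) + 1L]] <- data.frame(
      member = u, cons_id = id, slot = 0L,
      length = nchar(contigs$seq[[u]]), stringsAsFactors = FALSE)
  }
  Ttab <- do.call(rbind, rows)
  rownames(Ttab) <- NULL
  structure(list(seq = seqs, T = Ttab,
                 member_map = do.call(rbind, mmap),
                 C_hetero = C_het),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d consensus contigs (%s)\n", nrow(x$T),
              paste(names(table(x$T$class)), table(x$T$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Merge any input style into consensus contigs
#'
#' Paired-haplotype input goes straight to [build_consensus()] (the merge
#' is idempotent on such input). Pseudo-haplotype and haplotype-ignorant
#' input is first converted to paired-haplotype form via self-alignment,
#' opposite assignment and mincing.
#'
#' @param contigs A \code{contigset} from [read_assembly()].
#' @param config A \code{hapscaf_config}.
#' @param paf Optional precomputed self-alignment PAF.
#' @return List: \code{consensus} (a \code{consensus_set}),
#'   \code{provenance} (piece, source, offset, length; identity rows when
#'   no mincing occurred), \code{removed} (repeat contig ids).
#' @export
merge_haplotigs <- function(contigs, config = scaffold_config(),
                            paf = NULL) {
  paired_styles <- c("primary_bubble", "secondary_bubble", "non_bubble")
  if (all(contigs$info$style %in% paired_styles)) {
    prov <- data.frame(piece = contigs$info$id, source = contigs$info$id,
                       offset = 0, length = contigs$info$length,
                       stringsAsFactors = FALSE)
    return(list(consensus = build_consensus(contigs, config),
                provenance = prov, removed = character(0)))
  }
  al <- self_align_contigs(contigs, config, paf = paf)
  asg <- assign_opposites(contigs, al, config)
  minced <- mince_and_tag(contigs, asg, config)
  list(consensus = build_consensus(minced$contigs, config),
       provenance = minced$provenance, removed = asg$removed)
}

#' Write a consensus set to FASTA and a T-table TSV
#'
#' FASTA headers carry the T entry and class; the TSV has columns
#' consensus_id, member0, member1, class.
#'
#' @param cons A \code{consensus_set}.
#' @param out_fasta,out_tsv Output paths.
#' @export
write_consensus <- function(cons, out_fasta, out_tsv) {
  seqs <- cons$seq
  names(seqs) <- sprintf("%s members=%s,%s class=%s", cons$T$id,
                         cons$T$member0, cons$T$member1, cons$T$class)
  write_fasta_chr(seqs, out_fasta)
  utils::write.table(
    stats::setNames(cons$T, c("consensus_id", "member0", "member1", "class")),
    out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_fasta)
}

# Lift member-contig coordinates to consensus coordinates. Secondary-member
# positions are scaled proportionally onto the primary sequence.
member_to_consensus <- function(members, pos, cons) {
  mm <- cons$member_map
  idx <- match(members, mm$member)
  if (anyNA(idx))
    stop("link references unknown member contig: ",
         members[which(is.na(idx))[1L]], call. = FALSE)
  cons_id <- mm$cons_id[idx]
  len <- mm$length[idx]
  len0 <- stats::setNames(mm$length[mm$slot == 0L], mm$cons_id[mm$slot == 0L])
  l0 <- unname(len0[cons_id])
  newpos <- ifelse(mm$slot[idx] == 0L, pos,
                   pmin(floor(pos * l0 / pmax(len, 1)), l0 - 1))
  list(cons_id = cons_id, pos = pmax(pmin(newpos, l0 - 1), 0))
}

# Re-express (source contig, position) records against minced pieces.
remap_to_pieces <- function(seq_ids, pos, provenance) {
  pr <- provenance[order(provenance$source, provenance$offset), ]
  out_id <- rep(NA_character_, length(seq_ids))
  out_pos <- rep(NA_real_, length(pos))
  for (s in unique(seq_ids)) {
    rows <- pr[pr$source == s, , drop = FALSE]
    i <- which(seq_ids == s)
    if (!nrow(rows)) next
    idx <- findInterval(pos[i], rows$offset)
    ok <- idx >= 1L & pos[i] < rows$offset[pmax(idx, 1L)] +
      rows$length[pmax(idx, 1L)]
    out_id[i][ok] <- rows$piece[idx[ok]]
    out_pos[i][ok] <- pos[i][ok] - rows$offset[idx[ok]]
  }
  list(id = out_id, pos = out_pos)
}
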