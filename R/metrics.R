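# Assembly evaluation: N50, phasing accuracy from haplotype-specific
# markers, and truth-based misassembly / switch-error counts for simulated
# data. All metrics follow the convention of scoring sequences >= 500 bp.

#' N50 of a set of sequence lengths
#'
#' The length of the shortest sequence such that it and all longer
#' sequences cover at least half the assembly.
#'
#' @param lengths Positive lengths (bases).
#' @return N50 (bases).
#' @export
n50 <- function(lengths) {
  if (!length(lengths) || any(lengths <= 0))
    stop("lengths must be a nonempty vector of positive values",
         call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Phasing accuracy from haplotype-marker counts
#'
#' Per scaffold, the fraction of haplotype-specific markers belonging to
#' the majority haplotype, \code{max(n0, n1) / (n0 + n1)}; the overall
#' value weights scaffolds by their marker totals. Marker-free scaffolds
#' are excluded (NA overall if all are).
#'
#' @param markers Data frame with columns \code{scaffold},
#'   \code{n_hap0_markers}, \code{n_hap1_markers}.
#' @return List: \code{per_scaffold} (data frame with accuracy),
#'   \code{overall}.
#' @export
phasing_accuracy <- function(markers) {
  tot <- markers$n_hap0_markers + markers$n_hap1_markers
  acc <- ifelse(tot > 0,
                pmax(markers$n_hap0_markers, markers$n_hap1_markers) /
                  tot, NA_real_)
  per <- data.frame(markers, accuracy = acc)
  scored <- !is.na(acc)
  overall <- if (any(scored))
    sum(acc[scored] * tot[scored]) / sum(tot[scored]) else NA_real_
  list(per_scaffold = per, overall = overall)
}

# truth interval of a member contig (possibly a minced piece): its source
# fragment row shifted by the piece offset
member_truth <- function(members, fragments, provenance) {
  pr <- provenance[match(members, provenance$piece), , drop = FALSE]
  src <- ifelse(is.na(pr$source), members, pr$source)
  off <- ifelse(is.na(pr$offset), 0, pr$offset)
  plen <- pr$length
  fr <- fragments[match(src, fragments$contig_id), , drop = FALSE]
  len <- ifelse(is.na(plen), fr$end - fr$start, plen)
  data.frame(member = members, chrom = fr$chrom, hap = fr$hap,
             start = fr$start + off, end = fr$start + off + len,
             collapsed = fr$collapsed, stringsAsFactors = FALSE)
}

#' Truth-based misassembly and switch-error counts
#'
#' A misassembly is an adjacent scaffold member pair whose truth
#' coordinates are not collinear on one chromosome: different chromosome,
#' inconsistent orientation, or a positional step that deviates from
#' adjacency by more than \code{tolerance}. A switch error is an adjacent
#' pair of haplotype blocks in one emitted haplotype whose truth
#' haplotypes differ. Truth coordinates come from the simulator's fragment
#' table (each consensus contig is located via its primary member).
#'
#' @param scafset Final scaffolds.
#' @param cons The \code{consensus_set}.
#' @param fragments Simulator fragment truth table.
#' @param provenance Piece provenance from the merge stage.
#' @param phase_report Optional report from [phase_scaffolds()] for switch
#'   errors.
#' @param tolerance Position tolerance (bases).
#' @return List: \code{misassemblies}, \code{switch_errors},
#'   \code{breakpoints} (table of offending junctions).
#' @export
truth_errors <- function(scafset, cons, fragments, provenance,
                         phase_report = NULL, tolerance = 1e4) {
  m <- scafset$members
  ti <- match(m$cons_id, cons$T$id)
  tr <- member_truth(cons$T$member0[ti], fragments, provenance)
  if (anyNA(tr$chrom))
    stop("scaffold member without truth coordinates: ",
         tr$member[which(is.na(tr$chrom))[1L]], call. = FALSE)
  mis <- 0L
  bp <- list()
  for (s in unique(m$scaffold)) {
    i <- which(m$scaffold == s)
    if (length(i) < 2L) next
    for (k in seq_len(length(i) - 1L)) {
      a <- i[k]; b <- i[k + 1L]
      bad <- FALSE
      if (tr$chrom[a] != tr$chrom[b] || m$orient[a] != m$orient[b]) {
        bad <- TRUE
      } else if (m$orient[a] == "+") {
        bad <- abs(tr$start[b] - tr$end[a]) > tolerance
      } else {
        bad <- abs(tr$start[a] - tr$end[b]) > tolerance
      }
      if (bad) {
        mis <- mis + 1L
        bp[[length(bp) + 1L]] <- data.frame(
          scaffold = s, left = m$cons_id[a], right = m$cons_id[b],
          chrom_left = tr$chrom[a], chrom_right = tr$chrom[b],
          stringsAsFactors = FALSE)
      }
    }
  }
  sw <- 0L
  if (!is.null(phase_report)) {
    rep0 <- phase_report
    key <- paste(rep0$scaffold, rep0$piece)
    for (kp in unique(key)) {
      rows <- rep0[key == kp, , drop = FALSE]
      rows <- rows[order(rows$idx), , drop = FALSE]
      rows <- rows[rows$kind == "haplotype", , drop = FALSE]
      if (nrow(rows) < 2L) next
      ph <- ifelse(is.na(rows$phase), 0L, rows$phase)
      chosen <- ifelse(ph == 0L, rows$member0, rows$member1)
      tru <- member_truth(chosen, fragments, provenance)
      hap_seq <- tru$hap[!tru$collapsed]
      if (length(hap_seq) >= 2L)
        sw <- sw + sum(hap_seq[-1L] != hap_seq[-length(hap_seq)])
    }
  }
  list(misassemblies = mis, switch_errors = sw,
       breakpoints = if (length(bp)) do.call(rbind, bp) else NULL)
}

#' Haplotype-marker counts of phased output pieces
#'
#' Simulated-truth surrogate for hap-mer counting: for each emitted hap0
#' piece, heterozygous variant positions inside its chosen members are
#' attributed to the member's truth haplotype.
#'
#' @param phase_report Report from [phase_scaffolds()].
#' @param fragments Simulator fragment truth table.
#' @param provenance Piece provenance from the merge stage.
#' @param variants Simulator variant table.
#' @return Marker data frame for [phasing_accuracy()] (one row per piece).
#' @export
sim_hap_markers <- function(phase_report, fragments, provenance,
                            variants) {
  key <- paste(phase_report$scaffold, phase_report$piece)
  out <- list()
  for (kp in unique(key)) {
    rows <- phase_report[key == kp, , drop = FALSE]
    rows <- rows[rows$kind == "haplotype", , drop = FALSE]
    n0 <- 0L; n1 <- 0L
    if (nrow(rows)) {
      ph <- ifelse(is.na(rows$phase), 0L, rows$phase)
      chosen <- ifelse(ph == 0L, rows$member0, rows$member1)
      chosen <- chosen[!is.na(chosen) & chosen != "-"]
      tru <- member_truth(chosen, fragments, provenance)
      for (r in seq_len(nrow(tru))) {
        if (is.na(tru$chrom[r]) || tru$collapsed[r]) next
        v <- variants[variants$chrom == tru$chrom[r], , drop = FALSE]
        pos <- if (tru$hap[r] == 0L) v$pos0 else v$pos1
        cnt <- sum(!is.na(pos) & pos >= tru$start[r] & pos < tru$end[r])
        if (tru$hap[r] == 0L) n0 <- n0 + cnt else n1 <- n1 + cnt
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      scaffold = kp, n_hap0_markers = n0, n_hap1_markers = n1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
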