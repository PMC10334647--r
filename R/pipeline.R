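# End-to-end driver: merge -> long-read scaffold -> iterative Hi-C
# scaffold -> phase.

#' Run the full scaffolding and phasing pipeline
#'
#' Merges the input contigs into consensus contigs, scaffolds them with
#' long-read links (vetted by Hi-C), extends the scaffolds by iterative
#' Hi-C end-graph joining, and phases the result into two haplotypes.
#'
#' @param contigs A \code{contigset} from [read_assembly()].
#' @param hic_pairs Member-level Hi-C mapped pairs (data frame with
#'   \code{read_id, seq_a, pos_a, seq_b, pos_b}, as from [read_pairs()] or
#'   [contacts_to_pairs()]).
#' @param longread_paf Long-read alignments to member contigs (data frame
#'   from [read_paf()] or [truth_paf()]).
#' @param config A \code{hapscaf_config}.
#' @param paf Optional precomputed self-alignment PAF for the merge stage.
#' @return A \code{"hapscaf_result"} with elements \code{consensus},
#'   \code{provenance}, \code{removed}, \code{scaffolds} (a
#'   \code{scafset}), \code{phased} (hap0/hap1/report), \code{log},
#'   \code{config}.
#' @export
run_pipeline <- function(contigs, hic_pairs, longread_paf,
                         config = scaffold_config(), paf = NULL) {
  mg <- merge_haplotigs(contigs, config, paf = paf)
  cons <- mg$consensus
  prov <- mg$provenance
  minced <- any(prov$piece != prov$source)
  # evidence is expressed against input contigs; re-express against pieces
  remap_pairs <- function(p) {
    if (!minced) return(p)
    a <- remap_to_pieces(p$seq_a, p$pos_a, prov)
    b <- remap_to_pieces(p$seq_b, p$pos_b, prov)
    ok <- !is.na(a$id) & !is.na(b$id)
    data.frame(read_id = p$read_id[ok], seq_a = a$id[ok],
               pos_a = a$pos[ok], seq_b = b$id[ok], pos_b = b$pos[ok],
               stringsAsFactors = FALSE)
  }
  hic_pairs <- remap_pairs(hic_pairs)
  if (minced && nrow(longread_paf)) {
    # split alignment rows at piece boundaries via midpoint assignment
    mid <- remap_to_pieces(longread_paf$tname,
                           (longread_paf$tstart + longread_paf$tend) / 2,
                           prov)
    shift <- mid$pos - (longread_paf$tstart + longread_paf$tend) / 2
    ok <- !is.na(mid$id)
    longread_paf <- longread_paf[ok, , drop = FALSE]
    pr_len <- prov$length[match(mid$id[ok], prov$piece)]
    longread_paf$tname <- mid$id[ok]
    longread_paf$tstart <- pmax(longread_paf$tstart + shift[ok], 0)
    longread_paf$tend <- pmin(longread_paf$tend + shift[ok], pr_len)
    longread_paf$tlen <- pr_len
  }
  member_lens <- stats::setNames(cons$member_map$length,
                                 cons$member_map$member)
  contacts_mem <- collect_hic_contacts(hic_pairs, member_lens)
  contacts_cons <- contacts_to_consensus(contacts_mem, cons)
  sel <- select_long_read_alignments(longread_paf, config)
  mlinks <- longread_links(sel)
  cov <- consensus_coverage(sel, cons)
  scafs <- longread_scaffold(cons, mlinks, contacts_cons, config)
  hs <- hic_scaffold(scafs, cons, contacts_cons, mlinks, config,
                     coverage_cons = cov)
  member_seqs <- member_sequences(contigs, cons, prov)
  phased <- phase_scaffolds(hs$scafset, cons, member_seqs, mlinks,
                            contacts_mem, config)
  structure(list(consensus = cons, provenance = prov,
                 removed = mg$removed, scaffolds = hs$scafset,
                 phased = phased, log = hs$log, config = config,
                 member_seqs = member_seqs),
            class = "hapscaf_result")
}

# sequences of every member contig (pieces included), for phased output
member_sequences <- function(contigs, cons, provenance) {
  out <- character(0)
  for (i in seq_len(nrow(provenance))) {
    p <- provenance$piece[i]
    if (!(p %in% cons$member_map$member)) next
    src <- provenance$source[i]
    out[p] <- substr(contigs$seq[[src]], provenance$offset[i] + 1L,
                     provenance$offset[i] + provenance$length[i])
  }
  out
}

#' @export
print.hapscaf_result <- function(x, ...) {
  ns <- length(unique(x$scaffolds$members$scaffold))
  cat("hapscaf pipeline result\n")
  cat(sprintf("  consensus contigs: %d (%s)\n", nrow(x$consensus$T),
              paste(names(table(x$consensus$T$class)),
                    table(x$consensus$T$class), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  scaffolds: %d\n", ns))
  cat(sprintf("  phased pieces: %d (hap0 + hap1 FASTA records: %d)\n",
              length(x$phased$hap0),
              length(x$phased$hap0) + length(x$phased$hap1)))
  invisible(x)
}

#' @export
summary.hapscaf_result <- function(object, ...) {
  cons_len <- stats::setNames(nchar(object$consensus$seq),
                              names(object$consensus$seq))
  slen <- scaffold_lengths(object$scaffolds, cons_len)
  out <- list(n_scaffolds = length(slen),
              scaffold_lengths = sort(unname(slen), decreasing = TRUE),
              n50 = n50(unname(slen)),
              n_consensus = nrow(object$consensus$T),
              n_removed = length(object$removed),
              n_phased_pieces = length(object$phased$hap0))
  class(out) <- "summary.hapscaf_result"
  out
}

#' @export
print.summary.hapscaf_result <- function(x, ...) {
  cat(sprintf("scaffolds: %d (N50 %s bp)\n", x$n_scaffolds,
              format(x$n50, big.mark = ",")))
  cat(sprintf("consensus contigs: %d; removed repeats: %d\n",
              x$n_consensus, x$n_removed))
  cat(sprintf("phased pieces: %d\n", x$n_phased_pieces))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the consensus FASTA + T table, scaffold FASTA + AGP, phased
#' haplotype FASTAs and the phase report.
#'
#' @param result A \code{hapscaf_result}.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the named list of paths.
#' @export
write_result <- function(result, dir, prefix = "hapscaf") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    consensus_fasta = file.path(dir, paste0(prefix, "_consensus.fa")),
    consensus_tsv = file.path(dir, paste0(prefix, "_T.tsv")),
    scaffold_fasta = file.path(dir, paste0(prefix, "_scaffolds.fa")),
    scaffold_agp = file.path(dir, paste0(prefix, "_scaffolds.agp")),
    hap0 = file.path(dir, paste0(prefix, "_hap0.fasta")),
    hap1 = file.path(dir, paste0(prefix, "_hap1.fasta")),
    report = file.path(dir, paste0(prefix, "_phase_report.tsv")),
    provenance = file.path(dir, paste0(prefix, "_provenance.tsv")))
  write_consensus(result$consensus, paths$consensus_fasta,
                  paths$consensus_tsv)
  write_scaffolds(result$scaffolds, result$consensus$seq,
                  paths$scaffold_fasta, paths$scaffold_agp)
  write_fasta_chr(result$phased$hap0, paths$hap0)
  write_fasta_chr(result$phased$hap1, paths$hap1)
  utils::write.table(result$phased$report, paths$report, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$provenance, paths$provenance, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
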