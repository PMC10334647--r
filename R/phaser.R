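# Phasing: divide consensus scaffolds into haplotype blocks and assign
# each block's two members to consistent global phases using long-read and
# Hi-C links between member contigs. Consensus-kind short-read records
# never enter the phase link counts.

#' Extract haplotype blocks from a scaffold
#'
#' Each scaffold member expands to its T entry: \code{[u,v]} becomes a
#' haplotype block, \code{[u,-]} a haplotype block whose second sequence is
#' an N placeholder, \code{[u,u]} a homozygous block.
#'
#' @param scafset A \code{scafset}.
#' @param cons The \code{consensus_set} holding array T.
#' @return Data frame: scaffold, idx, cons_id, orient, gap_after,
#'   member0, member1, kind (\code{"haplotype"}/\code{"homozygous"}).
#' @export
extract_blocks <- function(scafset, cons) {
  m <- scafset$members
  ti <- match(m$cons_id, cons$T$id)
  if (anyNA(ti))
    stop("scaffold member without T entry: ",
         m$cons_id[which(is.na(ti))[1L]], call. = FALSE)
  data.frame(scaffold = m$scaffold, idx = m$idx, cons_id = m$cons_id,
             orient = m$orient, gap_after = m$gap_after,
             member0 = cons$T$member0[ti], member1 = cons$T$member1[ti],
             kind = ifelse(cons$T$class[ti] == "homo", "homozygous",
                           "haplotype"),
             stringsAsFactors = FALSE)
}

#' Count parallel and cross phase links between haplotype blocks
#'
#' Long-read links and Hi-C contacts whose two endpoints fall in members of
#' two different haplotype blocks of the same scaffold are tallied:
#' endpoints in the same slot (both member0 or both member1) support the
#' parallel path, mixed slots the cross path. Links touching homozygous
#' blocks, or records tagged \code{kind == "consensus"}, are ignored.
#'
#' @param blocks Output of [extract_blocks()].
#' @param member_links Long-read link records (columns ctg_a, ctg_b;
#'   an optional \code{kind} column is filtered for \code{"consensus"}).
#' @param contacts Member-level Hi-C contacts (seq_a, seq_b), or NULL.
#' @return Data frame: scaffold, i, j (block idx, i < j), parallel, cross.
#' @export
count_phase_links <- function(blocks, member_links = NULL,
                              contacts = NULL) {
  hb <- blocks[blocks$kind == "haplotype", , drop = FALSE]
  slot_of <- integer(0); blk_of <- integer(0); scaf_of <- character(0)
  add <- function(member, slot, idx, scaf) {
    ok <- !is.na(member) & member != "-"
    slot_of[member[ok]] <<- slot
    blk_of[member[ok]] <<- idx[ok]
    scaf_of[member[ok]] <<- scaf[ok]
  }
  add(hb$member0, 0L, hb$idx, hb$scaffold)
  add(hb$member1, 1L, hb$idx, hb$scaffold)
  ends <- function(a, b) data.frame(a = a, b = b, stringsAsFactors = FALSE)
  evid <- list()
  if (!is.null(member_links) && nrow(member_links)) {
    ml <- member_links
    if (!is.null(ml$kind)) ml <- ml[ml$kind != "consensus", , drop = FALSE]
    evid[[1L]] <- ends(ml$ctg_a, ml$ctg_b)
  }
  if (!is.null(contacts) && nrow(contacts))
    evid[[length(evid) + 1L]] <- ends(contacts$seq_a, contacts$seq_b)
  if (!length(evid))
    return(data.frame(scaffold = character(0), i = integer(0),
                      j = integer(0), parallel = integer(0),
                      cross = integer(0)))
  ev <- do.call(rbind, evid)
  ka <- match(ev$a, names(slot_of)); kb <- match(ev$b, names(slot_of))
  ok <- !is.na(ka) & !is.na(kb)
  ev <- ev[ok, , drop = FALSE]; ka <- ka[ok]; kb <- kb[ok]
  sa <- scaf_of[ka]; sb <- scaf_of[kb]
  ia <- blk_of[ka]; ib <- blk_of[kb]
  ok <- sa == sb & ia != ib
  if (!any(ok))
    return(data.frame(scaffold = character(0), i = integer(0),
                      j = integer(0), parallel = integer(0),
                      cross = integer(0)))
  sa <- sa[ok]
  i <- pmin(ia[ok], ib[ok]); j <- pmax(ia[ok], ib[ok])
  par <- slot_of[ka][ok] == slot_of[kb][ok]
  key <- paste(sa, i, j, sep = "\r")
  tot_p <- tapply(as.integer(par), key, sum)
  tot_c <- tapply(as.integer(!par), key, sum)
  parts <- do.call(rbind, strsplit(names(tot_p), "\r", fixed = TRUE))
  out <- data.frame(scaffold = parts[, 1L],
                    i = as.integer(parts[, 2L]),
                    j = as.integer(parts[, 3L]),
                    parallel = as.integer(tot_p),
                    cross = as.integer(tot_c),
                    stringsAsFactors = FALSE)
  out[order(out$scaffold, out$i, out$j), ]
}

#' Greedy phasing of haplotype blocks
#'
#' Within each scaffold, block pairs are processed in decreasing
#' \code{|parallel - cross|} (ties toward the smaller \code{(i, j)}). A
#' pair spanning two phase components merges them, flipping one component
#' when the cross path dominates; pairs with \code{parallel == cross} never
#' merge. Blocks left in singleton components are unphased.
#'
#' @param blocks Output of [extract_blocks()].
#' @param counts Output of [count_phase_links()].
#' @return \code{blocks} with added columns \code{comp} (component label,
#'   NA for homozygous blocks) and \code{phase} (0/1 relative to the
#'   component; NA when unphased).
#' @export
greedy_phase <- function(blocks, counts) {
  blocks$comp <- NA_character_
  blocks$phase <- NA_integer_
  for (s in unique(blocks$scaffold)) {
    hb <- which(blocks$scaffold == s & blocks$kind == "haplotype")
    if (!length(hb)) next
    idxs <- blocks$idx[hb]
    parent <- stats::setNames(idxs, idxs)      # union-find
    flip <- stats::setNames(rep(0L, length(idxs)), idxs)  # phase vs parent
    find <- function(x) {
      f <- 0L
      while (parent[[as.character(x)]] != x) {
        f <- xor(f, flip[[as.character(x)]])
        x <- parent[[as.character(x)]]
      }
      list(root = x, flip = f)
    }
    cn <- counts[counts$scaffold == s & counts$parallel != counts$cross, ,
                 drop = FALSE]
    if (nrow(cn)) {
      cn <- cn[order(-abs(cn$parallel - cn$cross), cn$i, cn$j), ]
      for (r in seq_len(nrow(cn))) {
        fi <- find(cn$i[r]); fj <- find(cn$j[r])
        if (fi$root == fj$root) next
        rel <- as.integer(cn$cross[r] > cn$parallel[r])
        # phase(j) = phase(i) XOR rel
        parent[[as.character(fj$root)]] <- fi$root
        flip[[as.character(fj$root)]] <-
          xor(xor(fi$flip, rel), fj$flip)
      }
    }
    roots <- vapply(idxs, function(x) find(x)$root, numeric(1L))
    phases <- vapply(idxs, function(x) as.integer(find(x)$flip),
                     integer(1L))
    comp_size <- table(roots)
    connected <- comp_size[as.character(roots)] >= 2L
    blocks$comp[hb] <- paste0(s, ":", roots)
    blocks$phase[hb] <- ifelse(connected, phases, NA_integer_)
    blocks$comp[hb][!connected] <- paste0(s, ":solo", idxs[!connected])
  }
  blocks
}

#' Emit phased haplotype scaffolds
#'
#' Scaffolds are divided between adjacent haplotype blocks belonging to
#' different phase components, except that an unphased block strictly
#' inside one component's span receives a seeded-random phase and causes no
#' division. Homozygous blocks are copied into both haplotype outputs and
#' attach to the surrounding piece. \code{[u,-]} blocks render their absent
#' member as an N run of equal length.
#'
#' @param scafset A \code{scafset}.
#' @param cons The \code{consensus_set}.
#' @param blocks Output of [greedy_phase()].
#' @param member_seqs Named member-contig sequences.
#' @param seed Seed for random phases of isolated interior blocks.
#' @return List: \code{hap0}, \code{hap1} (named sequence vectors, ids
#'   suffixed \code{_hap0}/\code{_hap1}), \code{report} (per-block table
#'   with piece, phase, component and random flag).
#' @export
emit_phased_scaffolds <- function(scafset, cons, blocks, member_seqs,
                                  seed = 1L) {
  set.seed(seed)
  hap0 <- character(0); hap1 <- character(0)
  report <- list()
  for (s in unique(blocks$scaffold)) {
    bs <- blocks[blocks$scaffold == s, , drop = FALSE]
    bs <- bs[order(bs$idx), , drop = FALSE]
    het <- which(bs$kind == "haplotype")
    # resolve isolated interior blocks: absorbed with a random phase
    comp <- bs$comp
    phase <- bs$phase
    random_flag <- rep(FALSE, nrow(bs))
    if (length(het) >= 3L) {
      for (t in seq_along(het)) {
        b <- het[t]
        if (!is.na(phase[b])) next
        if (t == 1L || t == length(het)) next
        prev <- het[t - 1L]; nxt <- het[t + 1L]
        if (comp[prev] == comp[nxt] && !is.na(phase[prev])) {
          comp[b] <- comp[prev]
          phase[b] <- sample(0:1, 1L)
          random_flag[b] <- TRUE
        }
      }
    }
    # piece boundaries between het blocks in different components
    piece <- integer(nrow(bs))
    cur <- 1L
    last_comp <- NA_character_
    for (r in seq_len(nrow(bs))) {
      if (bs$kind[r] == "haplotype") {
        if (!is.na(last_comp) && comp[r] != last_comp) cur <- cur + 1L
        last_comp <- comp[r]
      }
      piece[r] <- cur
    }
    for (p in unique(piece)) {
      rows <- which(piece == p)
      seq0 <- character(0); seq1 <- character(0)
      for (t in seq_along(rows)) {
        r <- rows[t]
        ph <- if (is.na(phase[r])) 0L else phase[r]
        pick <- function(slot) {
          mem <- if (slot == 0L) bs$member0[r] else bs$member1[r]
          if (bs$kind[r] == "homozygous") mem <- bs$member0[r]
          if (is.na(mem) || mem == "-") {
            present <- if (slot == 0L) bs$member1[r] else bs$member0[r]
            return(strrep("N", nchar(member_seqs[[present]])))
          }
          sq <- member_seqs[[mem]]
          if (bs$orient[r] == "-") sq <- revcomp(sq)
          sq
        }
        s0 <- pick(ph); s1 <- pick(1L - ph)
        gap <- if (t < length(rows) && bs$gap_after[r] > 0)
          strrep("N", bs$gap_after[r]) else ""
        seq0 <- c(seq0, s0, gap); seq1 <- c(seq1, s1, gap)
        report[[length(report) + 1L]] <- data.frame(
          scaffold = s, piece = p, idx = bs$idx[r], cons_id = bs$cons_id[r],
          member0 = bs$member0[r], member1 = bs$member1[r],
          kind = bs$kind[r], comp = comp[r], phase = phase[r],
          random = random_flag[r], stringsAsFactors = FALSE)
      }
      pid <- if (max(piece) == 1L) s else sprintf("%s_part%d", s, p)
      hap0[paste0(pid, "_hap0")] <- paste(seq0, collapse = "")
      hap1[paste0(pid, "_hap1")] <- paste(seq1, collapse = "")
    }
  }
  list(hap0 = hap0, hap1 = hap1, report = do.call(rbind, report))
}

#' Phase consensus scaffolds into two haplotypes
#'
#' Runs block extraction, phase-link counting, greedy phasing and phased
#' output emission.
#'
#' @param scafset Scaffolds from the scaffolding stage.
#' @param cons The \code{consensus_set}.
#' @param member_seqs Named member-contig sequences.
#' @param member_links Long-read link records (member coordinates).
#' @param contacts Member-level Hi-C contacts.
#' @param config A \code{hapscaf_config} (supplies the seed).
#' @return As [emit_phased_scaffolds()], plus \code{blocks} and
#'   \code{counts}.
#' @export
phase_scaffolds <- function(scafset, cons, member_seqs,
                            member_links = NULL, contacts = NULL,
                            config = scaffold_config()) {
  blocks <- extract_blocks(scafset, cons)
  counts <- count_phase_links(blocks, member_links, contacts)
  phased <- greedy_phase(blocks, counts)
  out <- emit_phased_scaffolds(scafset, cons, phased, member_seqs,
                               seed = config$seed)
  out$blocks <- phased
  out$counts <- counts
  out
}
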