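# Two-stage consensus scaffolding: long-read graph scaffolding with
# misassembly awareness, then iterative Hi-C end-graph joining with dual
# (Hi-C + long-read) validation of every candidate junction.

other_end <- function(e) ifelse(e == "5p", "3p", "5p")

reverse_members <- function(m) {
  n <- nrow(m)
  out <- m[rev(seq_len(n)), , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  ga <- m$gap_after
  out$gap_after <- if (n > 1L) c(rev(ga[-n]), 0L) else ga
  out$idx <- seq_len(n)
  rownames(out) <- NULL
  out
}

# contacts (consensus coords) -> scaffold coords
lift_contacts <- function(contacts, placement) {
  idx_a <- match(contacts$seq_a, placement$cons_id)
  idx_b <- match(contacts$seq_b, placement$cons_id)
  ok <- !is.na(idx_a) & !is.na(idx_b)
  contacts <- contacts[ok, , drop = FALSE]
  idx_a <- idx_a[ok]; idx_b <- idx_b[ok]
  lift1 <- function(idx, pos) {
    fwd <- placement$orient[idx] == "+"
    placement$offset[idx] +
      ifelse(fwd, pos, placement$len[idx] - 1 - pos)
  }
  data.frame(seq_a = placement$scaffold[idx_a],
             pos_a = lift1(idx_a, contacts$pos_a),
             seq_b = placement$scaffold[idx_b],
             pos_b = lift1(idx_b, contacts$pos_b),
             stringsAsFactors = FALSE)
}

# member-level long-read links -> scaffold end-pair counts
links_to_scaffold_ends <- function(links, cons, placement) {
  empty <- data.frame(id_a = character(0), end_a = character(0),
                      id_b = character(0), end_b = character(0),
                      n = integer(0))
  if (!nrow(links)) return(empty)
  mm <- cons$member_map
  cons_of <- stats::setNames(mm$cons_id, mm$member)
  lift_end <- function(ctg, end) {
    ci <- cons_of[ctg]
    idx <- match(ci, placement$cons_id)
    scaf <- placement$scaffold[idx]
    e <- ifelse(placement$orient[idx] == "+", end, other_end(end))
    list(scaf = scaf, end = e, ok = !is.na(idx))
  }
  a <- lift_end(links$ctg_a, links$end_a)
  b <- lift_end(links$ctg_b, links$end_b)
  ok <- a$ok & b$ok & a$scaf != b$scaf
  if (!any(ok)) return(empty)
  sa <- a$scaf[ok]; ea <- a$end[ok]; sb <- b$scaf[ok]; eb <- b$end[ok]
  flip <- sa > sb
  id_a <- ifelse(flip, sb, sa); id_b <- ifelse(flip, sa, sb)
  end_a <- ifelse(flip, eb, ea); end_b <- ifelse(flip, ea, eb)
  key <- paste(id_a, end_a, id_b, end_b, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  data.frame(id_a = parts[, 1L], end_a = parts[, 2L],
             id_b = parts[, 3L], end_b = parts[, 4L],
             n = as.integer(tab), stringsAsFactors = FALSE)
}

# member-level long-read links -> scaffold coordinates (positions kept)
member_links_to_scaffold_pos <- function(links, cons, placement) {
  empty <- data.frame(scaf_a = character(0), pos_a = numeric(0),
                      scaf_b = character(0), pos_b = numeric(0))
  if (!nrow(links)) return(empty)
  a <- member_to_consensus(links$ctg_a, links$pos_a, cons)
  b <- member_to_consensus(links$ctg_b, links$pos_b, cons)
  idx_a <- match(a$cons_id, placement$cons_id)
  idx_b <- match(b$cons_id, placement$cons_id)
  ok <- !is.na(idx_a) & !is.na(idx_b)
  if (!any(ok)) return(empty)
  lift1 <- function(idx, pos) {
    fwd <- placement$orient[idx] == "+"
    placement$offset[idx] + ifelse(fwd, pos, placement$len[idx] - 1 - pos)
  }
  data.frame(scaf_a = placement$scaffold[idx_a[ok]],
             pos_a = lift1(idx_a[ok], a$pos[ok]),
             scaf_b = placement$scaffold[idx_b[ok]],
             pos_b = lift1(idx_b[ok], b$pos[ok]),
             stringsAsFactors = FALSE)
}

#' Insert-length tolerance of a paired library
#'
#' @param a Mean insert size (bases).
#' @param d Insert-size standard deviation (bases).
#' @return \code{a + 3 * d}.
#' @export
insert_tolerance <- function(a, d) a + 3 * d

# Build the tentative two-scaffold junction matrix for ends
# (idA, endA) -- (idB, endB), orienting each scaffold so the joined ends
# meet, and score it. Returns NULL when either side has no complete bin.
junction_scores <- function(idA, endA, idB, endB, scaf_contacts,
                            scaf_len, config) {
  lenA <- scaf_len[[idA]]; lenB <- scaf_len[[idB]]
  bs <- config$bin_size
  if (floor(lenA / bs) < 1 || floor(lenB / bs) < 1) return(NULL)
  orientA <- if (endA == "3p") "+" else "-"
  orientB <- if (endB == "5p") "+" else "-"
  cc <- scaf_contacts[scaf_contacts$seq_a %in% c(idA, idB) &
                        scaf_contacts$seq_b %in% c(idA, idB), , drop = FALSE]
  tr <- function(scaf, pos) {
    isA <- scaf == idA
    out <- numeric(length(pos))
    pA <- pos[isA]; pB <- pos[!isA]
    out[isA] <- if (orientA == "+") pA else lenA - 1 - pA
    out[!isA] <- if (orientB == "+") pB else lenB - 1 - pB
    out
  }
  pos_a <- tr(cc$seq_a, cc$pos_a)
  pos_b <- tr(cc$seq_b, cc$pos_b)
  joined <- data.frame(
    seq_a = ifelse(cc$seq_a == idA, "A", "B"), pos_a = pos_a,
    seq_b = ifelse(cc$seq_b == idA, "A", "B"), pos_b = pos_b,
    stringsAsFactors = FALSE)
  mat <- build_contact_matrix(c(A = lenA, B = lenB), joined, bs)
  if (is.null(mat$junction_bin) || mat$junction_bin < 1L ||
      mat$junction_bin >= mat$n_bins) return(NULL)
  separation_scores(mat, config$k_max)
}

#' Long-read (and PE) check of a candidate scaffold junction
#'
#' Implements the three-step decision: (1) links supporting the candidate
#' end pair above \code{min_link} make it correct; (2) otherwise a
#' better-supported pairing of the same two scaffolds replaces it; (3)
#' otherwise reads linking the end region elsewhere indicate a misassembly
#' near the end -- the candidate region (for paired libraries, insert
#' tolerance \code{a + 3d} from the mapped start; for long reads, up to the
#' projected partner position) is split at its minimum-coverage point and
#' the edge accepted post-correction; with no such evidence the edge is
#' erroneous.
#'
#' @param idA,endA,idB,endB The candidate junction (scaffold id + end).
#' @param end_links Scaffold end-pair link counts.
#' @param bridge_links Member links lifted to scaffold coordinates
#'   (columns scaf_a, pos_a, scaf_b, pos_b), used for the end-window
#'   misassembly search.
#' @param coverage Named list of per-base scaffold coverage vectors (or
#'   NULL to skip the correction search).
#' @param config A \code{hapscaf_config}.
#' @return List with \code{verdict} (\code{"correct"},
#'   \code{"replaced_by"} or \code{"erroneous"}) and optionally
#'   \code{replacement} (end pair) or \code{split} (scaffold, position).
#' @export
check_edge_longread <- function(idA, endA, idB, endB, end_links,
                                bridge_links = NULL, coverage = NULL,
                                config = scaffold_config()) {
  count_for <- function(ea, eb) {
    a <- min(idA, idB); b <- max(idA, idB)
    if (idA > idB) { tmp <- ea; ea <- eb; eb <- tmp }
    hit <- end_links$id_a == a & end_links$id_b == b &
      end_links$end_a == ea & end_links$end_b == eb
    if (any(hit)) sum(end_links$n[hit]) else 0L
  }
  if (count_for(endA, endB) > config$min_link)
    return(list(verdict = "correct"))
  alts <- list(c(endA, other_end(endB)), c(other_end(endA), endB),
               c(other_end(endA), other_end(endB)))
  alt_n <- vapply(alts, function(p) count_for(p[1L], p[2L]), numeric(1L))
  if (any(alt_n > config$min_link)) {
    best <- which.max(alt_n)
    return(list(verdict = "replaced_by",
                replacement = list(endA = alts[[best]][1L],
                                   endB = alts[[best]][2L])))
  }
  # (3) search the end windows for a misassembly indicated by reads whose
  # other alignment lies on a third scaffold
  if (!is.null(bridge_links) && !is.null(coverage)) {
    for (side in list(list(id = idA, end = endA),
                      list(id = idB, end = endB))) {
      cov <- coverage[[side$id]]
      if (is.null(cov)) next
      L <- length(cov)
      win <- if (side$end == "5p") c(0, min(config$end_search_window, L))
      else c(max(0, L - config$end_search_window), L)
      sel_a <- bridge_links$scaf_a == side$id &
        bridge_links$pos_a >= win[1L] & bridge_links$pos_a < win[2L] &
        !(bridge_links$scaf_b %in% c(idA, idB))
      sel_b <- bridge_links$scaf_b == side$id &
        bridge_links$pos_b >= win[1L] & bridge_links$pos_b < win[2L] &
        !(bridge_links$scaf_a %in% c(idA, idB))
      pos <- c(bridge_links$pos_a[sel_a], bridge_links$pos_b[sel_b])
      if (!length(pos)) next
      lo <- max(win[1L], min(pos)); hi <- win[2L]
      if (hi - lo < 2) next
      seg <- cov[(lo + 1L):hi]
      mins <- which(seg == min(seg))
      bp <- lo + mins[ceiling(length(mins) / 2)]  # plateau midpoint
      return(list(verdict = "correct",
                  split = list(scaffold = side$id, pos = bp)))
    }
  }
  list(verdict = "erroneous")
}

# consecutive-end chain assembly from a set of accepted end edges
chain_scaffolds <- function(ids, edges, gaps, prefix) {
  # edges: data.frame(id_a, end_a, id_b, end_b, gap)
  edge_of <- list()
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    edge_of[[paste(edges$id_a[i], edges$end_a[i])]] <- i
    edge_of[[paste(edges$id_b[i], edges$end_b[i])]] <- i
  }
  used <- logical(length(ids)); names(used) <- ids
  rows <- list(); sn <- 0L
  free_end <- function(id) {
    for (e in c("5p", "3p"))
      if (is.null(edge_of[[paste(id, e)]])) return(e)
    NA_character_
  }
  start_order <- ids
  for (s in start_order) {
    if (used[s]) next
    fe <- free_end(s)
    if (is.na(fe)) next  # in a cycle; handled below
    sn <- sn + 1L
    scaf <- sprintf("%s%04d", prefix, sn)
    cur <- s
    orient <- if (fe == "5p") "+" else "-"
    idx <- 0L
    repeat {
      used[cur] <- TRUE
      idx <- idx + 1L
      exit_end <- if (orient == "+") "3p" else "5p"
      ei <- edge_of[[paste(cur, exit_end)]]
      gap <- 0L
      nxt <- NULL
      if (!is.null(ei)) {
        e <- edges[ei, ]
        gap <- max(1L, round(e$gap))
        if (e$id_a == cur && e$end_a == exit_end) {
          nxt <- e$id_b; nxt_in <- e$end_b
        } else {
          nxt <- e$id_a; nxt_in <- e$end_a
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = scaf, idx = idx, cons_id = cur, orient = orient,
        gap_after = if (is.null(nxt)) 0L else gap,
        stringsAsFactors = FALSE)
      if (is.null(nxt)) break
      cur <- nxt
      orient <- if (nxt_in == "5p") "+" else "-"
    }
  }
  # remaining contigs sit on cycles: break the weakest edge of each
  if (any(!used)) {
    cyc <- names(used)[!used]
    in_cyc <- edges$id_a %in% cyc & edges$id_b %in% cyc
    if (any(in_cyc)) {
      weakest <- which(in_cyc)[which.min(edges$n[in_cyc])]
      edges2 <- edges[-weakest, , drop = FALSE]
      sub <- chain_scaffolds(cyc, edges2[edges2$id_a %in% cyc &
                                           edges2$id_b %in% cyc, ,
                                         drop = FALSE],
                             gaps, paste0(prefix, "c"))
      rows[[length(rows) + 1L]] <- sub$members
    } else {
      for (s in cyc) {
        sn <- sn + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sprintf("%s%04d", prefix, sn), idx = 1L,
          cons_id = s, orient = "+", gap_after = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  new_scafset(do.call(rbind, rows))
}

#' Scaffold consensus contigs with long-read links
#'
#' Aggregated long-read (and PE) links between consensus contig ends form a
#' graph; only unambiguous edges (each involved end has exactly one
#' incident edge above \code{min_link}) are kept, each is vetted with the
#' Hi-C erroneous-edge test at its tentative junction, and the surviving
#' non-branching chains are merged into scaffolds with the median link gap
#' (floor 1 N) between members.
#'
#' @param cons A \code{consensus_set}.
#' @param member_links Long-read links from [longread_links()] (member
#'   coordinates); PE links may be pooled in.
#' @param contacts_cons Hi-C contacts in consensus coordinates (or NULL to
#'   skip the Hi-C vetting).
#' @param config A \code{hapscaf_config}.
#' @return A \code{scafset} (one scaffold per chain; singletons for
#'   unjoined contigs).
#' @export
longread_scaffold <- function(cons, member_links, contacts_cons = NULL,
                              config = scaffold_config()) {
  ids <- cons$T$id
  edges <- links_to_consensus_edges(member_links, cons)
  edges <- edges[edges$n > config$min_link, , drop = FALSE]
  if (nrow(edges)) {
    node_a <- paste(edges$id_a, edges$end_a)
    node_b <- paste(edges$id_b, edges$end_b)
    deg <- table(c(node_a, node_b))
    keep <- deg[node_a] == 1L & deg[node_b] == 1L
    edges <- edges[keep, , drop = FALSE]
  }
  if (nrow(edges) && !is.null(contacts_cons)) {
    scaf_len <- stats::setNames(nchar(cons$seq), names(cons$seq))
    ok <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      sc <- junction_scores(edges$id_a[i], edges$end_a[i],
                            edges$id_b[i], edges$end_b[i],
                            data.frame(seq_a = contacts_cons$seq_a,
                                       pos_a = contacts_cons$pos_a,
                                       seq_b = contacts_cons$seq_b,
                                       pos_b = contacts_cons$pos_b),
                            scaf_len, config)
      ok[i] <- is.null(sc) ||
        !is_erroneous_edge_hic(sc, config$s_threshold, config$r_threshold)
    }
    edges <- edges[ok, , drop = FALSE]
  }
  chain_scaffolds(ids, edges, NULL, "ls")
}

# split a scaffold before member index at_idx (1-based; 2..n)
split_scaffold <- function(scafset, scaf, at_idx, new_ids) {
  m <- scafset$members
  i <- which(m$scaffold == scaf)
  stopifnot(at_idx > 1L, at_idx <= length(i))
  left <- m[i[seq_len(at_idx - 1L)], , drop = FALSE]
  right <- m[i[at_idx:length(i)], , drop = FALSE]
  left$scaffold <- new_ids[1L]; right$scaffold <- new_ids[2L]
  left$idx <- seq_len(nrow(left)); right$idx <- seq_len(nrow(right))
  left$gap_after[nrow(left)] <- 0L
  rest <- m[m$scaffold != scaf, , drop = FALSE]
  new_scafset(rbind(rest, left, right))
}

# Hi-C misassembly detection + correction pass over every scaffold:
# flagged bins are resolved to the member boundary nearest the
# minimum-coverage point inside the bin (consensus contigs are atomic).
misassembly_correction <- function(scafset, cons, contacts_cons, config,
                                   coverage_cons = NULL) {
  counter <- 0L
  repeat {
    cons_len <- stats::setNames(nchar(cons$seq), names(cons$seq))
    pl <- scaffold_placement(scafset, cons_len)
    slen <- scaffold_lengths(scafset, cons_len)
    sc_contacts <- lift_contacts(contacts_cons, pl)
    mats <- list()
    for (s in names(slen)) {
      if (floor(slen[[s]] / config$bin_size) < config$k_max + 1L) next
      cc <- sc_contacts[sc_contacts$seq_a == s & sc_contacts$seq_b == s, ,
                        drop = FALSE]
      mats[[s]] <- build_contact_matrix(stats::setNames(slen[s], s), cc,
                                        config$bin_size)
    }
    if (!length(mats)) return(scafset)
    qual <- names(mats)[slen[names(mats)] >= config$min_matrix_scaffold]
    if (!length(qual)) qual <- names(mats)
    mu_all <- global_distance_profile(mats[qual], config$k_max)
    did_split <- FALSE
    for (s in names(mats)) {
      prof <- misassembly_scores(mats[[s]], mu_all, config$k_max)
      sel <- select_threshold(prof, mats[[s]], config)
      if (!length(sel$flagged)) next
      b <- sel$flagged[1L]
      # minimum-coverage position inside the flagged bin
      lo <- b * config$bin_size; hi <- min((b + 1) * config$bin_size,
                                           slen[[s]])
      target <- (lo + hi) / 2
      if (!is.null(coverage_cons)) {
        cov <- scaffold_coverage_one(s, pl, coverage_cons)
        seg <- cov[(lo + 1L):hi]
        mins <- which(seg == min(seg))
        target <- lo + mins[ceiling(length(mins) / 2)]
      }
      mi <- pl[pl$scaffold == s, , drop = FALSE]
      if (nrow(mi) < 2L) next
      bounds <- mi$offset[-1L]
      at <- which.min(abs(bounds - target)) + 1L
      counter <- counter + 1L
      scafset <- split_scaffold(scafset, s, at,
                                sprintf("%s.m%d", s, c(1L, 2L) + counter))
      did_split <- TRUE
      break
    }
    if (!did_split) return(scafset)
  }
}

scaffold_coverage_one <- function(scaf, placement, coverage_cons) {
  mi <- placement[placement$scaffold == scaf, , drop = FALSE]
  n <- mi$scaf_len[1L]
  cov <- numeric(n)
  for (i in seq_len(nrow(mi))) {
    v <- coverage_cons[[mi$cons_id[i]]]
    if (is.null(v)) v <- numeric(mi$len[i])
    if (mi$orient[i] == "-") v <- rev(v)
    cov[(mi$offset[i] + 1L):(mi$offset[i] + mi$len[i])] <- v
  }
  cov
}

#' One Hi-C end-graph scaffolding round at window length L
#'
#' Builds the end-node graph (edge weight = Hi-C pairs with both ends
#' within \code{L} of the respective scaffold ends), filters edges below
#' the weight threshold, then repeatedly takes the heaviest edge, vets it
#' with the Hi-C separation-score test (and optionally the long-read
#' check), and either deletes it or joins the two scaffolds end-to-end
#' with a fixed-N gap, until the graph is stable.
#'
#' @param scafset Current scaffolds.
#' @param cons A \code{consensus_set}.
#' @param contacts_cons Hi-C contacts in consensus coordinates.
#' @param member_links Long-read links (member coordinates).
#' @param L End-window length (bases).
#' @param config A \code{hapscaf_config}.
#' @param check_long_reads Apply the long-read edge check.
#' @param coverage_cons Optional per-consensus coverage vectors.
#' @return List: \code{scafset}, \code{log} (decision rows).
#' @export
hic_scaffold_round <- function(scafset, cons, contacts_cons, member_links,
                               L, config = scaffold_config(),
                               check_long_reads = TRUE,
                               coverage_cons = NULL) {
  cons_len <- stats::setNames(nchar(cons$seq), names(cons$seq))
  wmin <- if (L < config$large_L_cutoff) config$hic_edge_min_weight_small_L
  else config$hic_edge_min_weight_large_L
  rejected <- character(0)
  log <- list()
  join_n <- 0L
  repeat {
    pl <- scaffold_placement(scafset, cons_len)
    slen <- scaffold_lengths(scafset, cons_len)
    cc <- lift_contacts(contacts_cons, pl)
    inter <- cc[cc$seq_a != cc$seq_b, , drop = FALSE]
    if (!nrow(inter)) break
    ends_of <- function(scaf, pos) {
      l <- slen[scaf]
      list(e5 = pos < L, e3 = l - pos <= L)
    }
    ea <- ends_of(inter$seq_a, inter$pos_a)
    eb <- ends_of(inter$seq_b, inter$pos_b)
    combos <- list(c("5p", "5p"), c("5p", "3p"), c("3p", "5p"),
                   c("3p", "3p"))
    keys <- character(0)
    for (cmb in combos) {
      fa <- if (cmb[1L] == "5p") ea$e5 else ea$e3
      fb <- if (cmb[2L] == "5p") eb$e5 else eb$e3
      sel <- which(fa & fb)
      if (!length(sel)) next
      a_id <- inter$seq_a[sel]; b_id <- inter$seq_b[sel]
      a_e <- rep(cmb[1L], length(sel)); b_e <- rep(cmb[2L], length(sel))
      flip <- a_id > b_id
      keys <- c(keys, paste(ifelse(flip, b_id, a_id),
                            ifelse(flip, b_e, a_e),
                            ifelse(flip, a_id, b_id),
                            ifelse(flip, a_e, b_e), sep = "\r"))
    }
    if (!length(keys)) break
    wt <- sort(table(keys), decreasing = TRUE)
    wt <- wt[wt >= wmin]
    wt <- wt[!(names(wt) %in% rejected)]
    if (!length(wt)) break
    # deterministic max: weight desc, then lexicographic key
    ord <- order(-as.numeric(wt), names(wt))
    key <- names(wt)[ord[1L]]
    w <- as.numeric(wt[ord[1L]])
    p <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    idA <- p[1L]; endA <- p[2L]; idB <- p[3L]; endB <- p[4L]
    sc <- junction_scores(idA, endA, idB, endB, cc, slen, config)
    bad_hic <- !is.null(sc) &&
      is_erroneous_edge_hic(sc, config$s_threshold, config$r_threshold)
    verdict <- if (bad_hic) "erroneous_hic" else "ok"
    split_req <- NULL
    if (!bad_hic && check_long_reads) {
      end_links <- links_to_scaffold_ends(member_links, cons, pl)
      bridges <- member_links_to_scaffold_pos(member_links, cons, pl)
      covs <- if (!is.null(coverage_cons))
        stats::setNames(lapply(c(idA, idB), scaffold_coverage_one,
                               placement = pl,
                               coverage_cons = coverage_cons),
                        c(idA, idB)) else NULL
      lr <- check_edge_longread(idA, endA, idB, endB, end_links,
                                bridge_links = bridges, coverage = covs,
                                config = config)
      if (lr$verdict == "replaced_by") {
        endA <- lr$replacement$endA
        endB <- lr$replacement$endB
        verdict <- "replaced"
      } else if (lr$verdict == "erroneous") {
        verdict <- "erroneous_longread"
      } else if (!is.null(lr$split)) {
        # misassembly near an end: split there first; the join candidates
        # are re-derived on the next iteration
        mi <- pl[pl$scaffold == lr$split$scaffold, , drop = FALSE]
        if (nrow(mi) >= 2L) {
          bounds <- mi$offset[-1L]
          at <- which.min(abs(bounds - lr$split$pos)) + 1L
          join_n <- join_n + 1L
          scafset <- split_scaffold(
            scafset, lr$split$scaffold, at,
            sprintf("%s.s%d", lr$split$scaffold, c(1L, 2L) + join_n))
          log[[length(log) + 1L]] <- data.frame(
            L = L, id_a = idA, end_a = endA, id_b = idB, end_b = endB,
            weight = w, verdict = "split_correction",
            stringsAsFactors = FALSE)
          next
        }
      }
    }
    log[[length(log) + 1L]] <- data.frame(
      L = L, id_a = idA, end_a = endA, id_b = idB, end_b = endB,
      weight = w, verdict = verdict, stringsAsFactors = FALSE)
    if (verdict %in% c("erroneous_hic", "erroneous_longread")) {
      rejected <- c(rejected, key)
      next
    }
    # join: orient A so endA is rightmost, B so endB is leftmost
    m <- scafset$members
    mA <- m[m$scaffold == idA, , drop = FALSE]
    mB <- m[m$scaffold == idB, , drop = FALSE]
    if (endA == "5p") mA <- reverse_members(mA)
    if (endB == "3p") mB <- reverse_members(mB)
    mA$gap_after[nrow(mA)] <- config$hic_join_gap
    join_n <- join_n + 1L
    new_id <- sprintf("%s.j%d", idA, join_n)
    joined <- rbind(mA, mB)
    joined$scaffold <- new_id
    joined$idx <- seq_len(nrow(joined))
    scafset <- new_scafset(rbind(m[!(m$scaffold %in% c(idA, idB)), ,
                                   drop = FALSE], joined))
  }
  list(scafset = scafset,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Iterative Hi-C scaffolding over the full L schedule
#'
#' For each window length \code{L} in the schedule, first runs Hi-C
#' misassembly detection/correction on every scaffold, then an end-graph
#' joining round with the long-read check enabled. The complete schedule is
#' then repeated once more without the long-read check, so that joins
#' across long repeats unreachable by long reads are still made (the Hi-C
#' erroneous-edge test always applies).
#'
#' @inheritParams hic_scaffold_round
#' @return List: \code{scafset} (final scaffolds), \code{log}.
#' @export
hic_scaffold <- function(scafset, cons, contacts_cons, member_links,
                         config = scaffold_config(),
                         coverage_cons = NULL) {
  logs <- list()
  for (pass in 1:2) {
    for (L in config$L_schedule) {
      scafset <- misassembly_correction(scafset, cons, contacts_cons,
                                        config, coverage_cons)
      r <- hic_scaffold_round(scafset, cons, contacts_cons, member_links,
                              L, config,
                              check_long_reads = (pass == 1L),
                              coverage_cons = coverage_cons)
      scafset <- r$scafset
      if (!is.null(r$log)) logs[[length(logs) + 1L]] <- r$log
    }
  }
  list(scafset = scafset,
       log = if (length(logs)) do.call(rbind, logs) else NULL)
}
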