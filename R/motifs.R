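## Census of signed structural motifs (cyclic and radial subgraphs of up
## to five nodes) among the hub nodes of a reconstructed network.
##
## Only the sign of a connection matters. Two equivalence rules apply:
## (i) within a reciprocal pair the direction of excitation vs inhibition
##     is not distinguished (A -+> B -|> A is the same as A -|> B -+> A),
##     so a reciprocal pair is one of three classes: EE (mutual
##     excitation), II (mutual inhibition), EI (counterbalanced);
## (ii) motifs obtained by permuting the reciprocal loops (or the directed
##     connections, for single-connection cycles) are the same motif, so
##     a class is identified by the *multiset* of its pair/edge classes.

#' Hub subset: nodes below the 50th percentile of ranked TNS
#'
#' The most strongly connected nodes: those whose rank does not exceed
#' the 50th-percentile rank index of the hierarchy curve (the smallest
#' rank whose cumulative TNS reaches half the network total).
#'
#' @param W Connectivity matrix.
#' @return Integer vector of node indices.
#' @export
hub_nodes <- function(W) {
  ns <- node_strengths(W)
  h <- hierarchy_curve(ns)
  ns$node[ns$rank <= h$p50_index]
}

#' Signed adjacency over a node subset
#'
#' An edge i -> j is present when `|W_ij|` exceeds `rel_threshold` times
#' the maximum off-diagonal magnitude within the subset; present edges
#' carry their sign, absent edges are zero. The threshold is a free
#' parameter of the census and is recorded in the result.
#'
#' @param W Connectivity matrix.
#' @param subset Node indices (default: [hub_nodes()] of `W`).
#' @param rel_threshold Relative magnitude threshold in `(0, 1)`
#'   (default 0.05).
#' @return Object of class `ou_signed_adjacency`: list with `signs`
#'   (matrix over the subset with entries in -1/0/+1, zero diagonal),
#'   `subset`, `rel_threshold`.
#' @export
signed_adjacency <- function(W, subset = NULL, rel_threshold = 0.05) {
  W <- as.matrix(unclass(W))
  if (is.null(subset)) subset <- hub_nodes(W)
  if (!length(subset)) stop("empty node subset")
  stopifnot(rel_threshold >= 0, rel_threshold < 1)
  B <- W[subset, subset, drop = FALSE]
  A <- abs(B); diag(A) <- 0
  thr <- rel_threshold * max(A)
  S <- sign(B) * (A > thr)
  diag(S) <- 0
  structure(list(signs = S, subset = subset, rel_threshold = rel_threshold),
            class = "ou_signed_adjacency")
}

## canonical class of a reciprocal pair of signs (both nonzero)
pair_class <- function(s_ij, s_ji) {
  if (s_ij > 0 && s_ji > 0) "EE"
  else if (s_ij < 0 && s_ji < 0) "II"
  else "EI"
}

## canonical multiset label
canonical_pattern <- function(parts) paste(sort(parts), collapse = "|")

## distinct cyclic arrangements of a node subset:
## undirected (reciprocal edges): rotations and reflections identified
## directed (single edges): rotations identified, orientation kept
cycle_arrangements <- function(nodes, directed) {
  n <- length(nodes)
  if (n == 2) return(list(nodes))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  rest <- perms(nodes[-1])
  arr <- lapply(rest, function(p) c(nodes[1], p))
  if (!directed) {
    ## identify each cycle with its reversal
    keep <- vapply(arr, function(a) a[2] < a[length(a)], logical(1))
    arr <- arr[keep]
  }
  arr
}

#' Census of signed cyclic and radial motifs
#'
#' Enumerates all placements of the catalogue's motif families over the
#' signed adjacency and counts occurrences per sign-pattern class:
#' \describe{
#'   \item{cyclic / reciprocal (2-5 nodes)}{nodes arranged in a cycle with
#'     every adjacent pair reciprocally connected (the 2-node case is a
#'     single reciprocal pair); class = multiset of pair classes.}
#'   \item{cyclic / single (3-5 nodes)}{a directed cycle of single
#'     connections; class = multiset of edge signs.}
#'   \item{radial / reciprocal (3-5 nodes)}{a center reciprocally linked
#'     to each leaf; connections among the leaves are not considered;
#'     class = multiset of spoke pair classes.}
#' }
#' An occurrence requires the motif's specified connections to be
#' present; connections the motif does not specify are ignored. The
#' probability of a class is `P = 100 * F / M` where `M` is the number of
#' possible placements of that topology and size (summable across
#' matrices of a group via [merge_census()]).
#'
#' @param sa An `ou_signed_adjacency`.
#' @param max_nodes Largest motif size (2 to 5).
#' @param max_placements Abort (with an explicit error, no silent
#'   sampling) if a family would require more placements than this.
#' @return Object of class `ou_motif_census`: data frame with columns
#'   `topology`, `style`, `size`, `pattern`, `F`, `M`, `P` (percent);
#'   one row per class observed plus zero rows are omitted. Attribute
#'   `placements` holds the per-family `M` table.
#' @export
motif_census <- function(sa, max_nodes = 5L, max_placements = 2e6) {
  stopifnot(inherits(sa, "ou_signed_adjacency"),
            max_nodes >= 2, max_nodes <= 5)
  S <- sa$signs
  h <- nrow(S)
  if (h < 2) stop("subset must contain at least 2 nodes")
  counts <- list()
  add <- function(topology, style, size, pattern) {
    key <- paste(topology, style, size, pattern, sep = "\r")
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  placements <- data.frame(topology = character(0), style = character(0),
                           size = integer(0), M = numeric(0))
  note_M <- function(topology, style, size, M) {
    placements <<- rbind(placements,
                         data.frame(topology = topology, style = style,
                                    size = size, M = M))
  }

  recip <- function(i, j) S[i, j] != 0 && S[j, i] != 0

  for (size in 2:max_nodes) {
    n_sub <- choose(h, size)
    ## --- cyclic, reciprocal ---
    n_arr <- if (size == 2) 1 else factorial(size - 1) / 2
    if (n_sub * n_arr > max_placements)
      stop("too many placements for exhaustive enumeration (size ", size, ")")
    note_M("cyclic", "reciprocal", size, n_sub * n_arr)
    if (size <= h) {
      subs <- utils::combn(h, size)
      for (c_i in seq_len(ncol(subs))) {
        nodes <- subs[, c_i]
        for (arr in cycle_arrangements(nodes, directed = FALSE)) {
          nxt <- c(arr[-1], arr[1])
          if (size == 2) { arr <- arr[1]; nxt <- nxt[1] }  # one pair, not two
          if (all(mapply(recip, arr, nxt))) {
            pat <- canonical_pattern(mapply(function(i, j)
              pair_class(S[i, j], S[j, i]), arr, nxt))
            add("cyclic", "reciprocal", size, pat)
          }
        }
      }
    }
    ## --- cyclic, single (size >= 3) ---
    if (size >= 3) {
      n_arr_d <- factorial(size - 1)
      if (n_sub * n_arr_d > max_placements)
        stop("too many placements for exhaustive enumeration (size ", size, ")")
      note_M("cyclic", "single", size, n_sub * n_arr_d)
      if (size <= h) {
        subs <- utils::combn(h, size)
        for (c_i in seq_len(ncol(subs))) {
          nodes <- subs[, c_i]
          for (arr in cycle_arrangements(nodes, directed = TRUE)) {
            nxt <- c(arr[-1], arr[1])
            sgn <- mapply(function(i, j) S[i, j], arr, nxt)
            if (all(sgn != 0)) {
              pat <- canonical_pattern(ifelse(sgn > 0, "E", "I"))
              add("cyclic", "single", size, pat)
            }
          }
        }
      }
    }
    ## --- radial, reciprocal (size >= 3): center + size-1 leaves ---
    if (size >= 3) {
      n_plc <- h * choose(h - 1, size - 1)
      if (n_plc > max_placements)
        stop("too many placements for exhaustive enumeration (size ", size, ")")
      note_M("radial", "reciprocal", size, n_plc)
      if (size <= h) {
        for (ctr in seq_len(h)) {
          leaves_all <- setdiff(seq_len(h), ctr)
          leaf_sets <- utils::combn(leaves_all, size - 1)
          for (c_i in seq_len(ncol(leaf_sets))) {
            lv <- leaf_sets[, c_i]
            if (all(vapply(lv, function(l) recip(ctr, l), logical(1)))) {
              pat <- canonical_pattern(vapply(lv, function(l)
                pair_class(S[ctr, l], S[l, ctr]), character(1)))
              add("radial", "reciprocal", size, pat)
            }
          }
        }
      }
    }
  }

  if (length(counts)) {
    keys <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
    df <- data.frame(topology = keys[, 1], style = keys[, 2],
                     size = as.integer(keys[, 3]), pattern = keys[, 4],
                     F = as.numeric(unlist(counts)))
  } else {
    df <- data.frame(topology = character(0), style = character(0),
                     size = integer(0), pattern = character(0),
                     F = numeric(0))
  }
  df <- merge(df, placements, by = c("topology", "style", "size"))
  df$P <- 100 * df$F / df$M
  df <- df[order(df$topology, df$style, df$size, -df$F), ]
  rownames(df) <- NULL
  structure(df, class = c("ou_motif_census", "data.frame"),
            placements = placements, rel_threshold = sa$rel_threshold)
}

#' Merge motif censuses across the matrices of a group
#'
#' Sums occurrence counts `F` and placement counts `M` over censuses
#' computed per matrix, so that probabilities are defined jointly over
#' the whole group (the per-matrix censuses remain available).
#'
#' @param ... `ou_motif_census` objects, or a single list of them.
#' @return A combined `ou_motif_census`.
#' @export
merge_census <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "ou_motif_census")) cs <- cs[[1]]
  stopifnot(all(vapply(cs, inherits, logical(1), "ou_motif_census")))
  all_f <- do.call(rbind, lapply(cs, function(x)
    as.data.frame(x)[, c("topology", "style", "size", "pattern", "F")]))
  F_agg <- stats::aggregate(F ~ topology + style + size + pattern,
                            data = all_f, FUN = sum)
  all_m <- do.call(rbind, lapply(cs, attr, "placements"))
  M_agg <- stats::aggregate(M ~ topology + style + size, data = all_m,
                            FUN = sum)
  df <- merge(F_agg, M_agg, by = c("topology", "style", "size"))
  df$P <- 100 * df$F / df$M
  df <- df[order(df$topology, df$style, df$size, -df$F), ]
  rownames(df) <- NULL
  structure(df, class = c("ou_motif_census", "data.frame"),
            placements = M_agg)
}

#' @export
print.ou_motif_census <- function(x, ...) {
  cat("Signed motif census (", nrow(x), " classes)\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}
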