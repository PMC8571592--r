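# ---- Transition rates through time -----------------------------------------
#
# Events from stochastic maps are timestamped at segment boundaries
# (absolute age, Myr before present), binned into B equal-width bins
# spanning [root age, 0], averaged over maps, and normalized by the total
# branch length falling inside each bin. Bins cover (younger, older] in age,
# so an event exactly on an interior bin edge is assigned to the older bin.

#' The six ordered transition types
#'
#' @return character vector, e.g. `"arboreal->semi-arboreal"`, in the fixed
#'   package order.
#' @export
transition_types <- function() {
  s <- arb_states()
  out <- character(0)
  for (i in 1:3) for (j in 1:3) if (i != j)
    out <- c(out, paste0(s[i], "->", s[j]))
  out
}

#' Equal-width time-bin grid over a tree's depth
#'
#' @param tree ultrametric `"phylo"` tree.
#' @param B number of bins (>= 1); the default used throughout the
#'   package is 50.
#' @param force_nonultrametric allow non-ultrametric trees (ages measured
#'   above the deepest tip).
#' @return object of class `"time_bin_grid"`: list with `B`, `width`,
#'   `edges` (length B+1, strictly decreasing from root age to 0) and
#'   `root_age`.
#' @export
make_time_bins <- function(tree, B = 50, force_nonultrametric = FALSE) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is_ultrametric_tree(tree) && !force_nonultrametric)
    stop("tree is not ultrametric; age-binning needs a chronogram ",
         "(use force_nonultrametric = TRUE to override)", call. = FALSE)
  ra <- root_age(tree)
  structure(list(B = as.integer(B), width = ra / B,
                 edges = seq(ra, 0, length.out = B + 1), root_age = ra),
            class = "time_bin_grid")
}

# Bin index for an age: bins cover (younger, older], older-inclusive.
.bin_of <- function(age, grid) {
  idx <- ceiling((grid$root_age - age) / grid$width)
  pmin(pmax(idx, 1L), grid$B)
}

#' Total branch length per time bin
#'
#' For each bin, the summed overlap between every edge's age interval and
#' the bin; conserves total tree length across bins.
#'
#' @param tree `"phylo"` tree.
#' @param grid a `"time_bin_grid"`.
#' @return numeric vector of length `grid$B` (Myr).
#' @export
branch_length_per_bin <- function(tree, grid) {
  ages <- node_ages(tree)
  older <- grid$edges[-length(grid$edges)]
  younger <- grid$edges[-1]
  out <- numeric(grid$B)
  for (e in seq_len(nrow(tree$edge))) {
    pa <- ages[tree$edge[e, 1]]; ca <- ages[tree$edge[e, 2]]
    ov <- pmax(0, pmin(pa, older) - pmax(ca, younger))
    out <- out + ov
  }
  out
}

# Event table of one map: age, from, to (observed indices), class switch flag.
.map_events <- function(map) {
  ages <- node_ages(map$tree)
  res <- list()
  for (e in seq_len(nrow(map$edge))) {
    seg <- map$segments[[e]]
    ns <- length(seg$state)
    if (ns < 2L) next
    t_par <- ages[map$edge[e, 1]]
    ev_age <- t_par - cumsum(seg$duration)[-ns]
    res[[length(res) + 1L]] <- data.frame(
      age = ev_age,
      from = .observed_state(seg$state[-ns]),
      to = .observed_state(seg$state[-1L]))
  }
  if (!length(res))
    return(data.frame(age = numeric(0), from = integer(0), to = integer(0)))
  do.call(rbind, res)
}

#' Mean transition counts per time bin
#'
#' Averages, over maps, the number of transition events whose absolute age
#' falls in each bin. Hidden-class switches (observed state unchanged) are
#' excluded. With `by_type = TRUE` a 6 x B matrix (one row per ordered
#' transition type) is returned; otherwise the per-bin totals.
#'
#' @param maps a `"simmap_set"` or list of `"stoch_map"`s on the grid's tree.
#' @param grid a `"time_bin_grid"` for that tree.
#' @param by_type split counts by ordered transition type.
#' @return numeric matrix (6 x B) or vector (length B).
#' @export
transitions_per_bin <- function(maps, grid, by_type = TRUE) {
  maps <- .as_map_list(maps)
  tol <- 1e-8 * max(grid$root_age, 1)
  acc <- matrix(0, 6L, grid$B, dimnames = list(transition_types(), NULL))
  pair_row <- matrix(NA_integer_, 3, 3)
  pair_row[t(matrix(c(1,2, 1,3, 2,1, 2,3, 3,1, 3,2), 2))] <- 1:6
  for (mp in maps) {
    ev <- .map_events(mp)
    if (!nrow(ev)) next
    keep <- ev$from != ev$to
    ev <- ev[keep, , drop = FALSE]
    if (!nrow(ev)) next
    if (any(ev$age < -tol | ev$age > grid$root_age + tol))
      stop("corrupt map: event age outside [root age, 0]", call. = FALSE)
    ev$age <- pmin(pmax(ev$age, 0), grid$root_age)
    bins <- .bin_of(ev$age, grid)
    rows <- pair_row[cbind(ev$from, ev$to)]
    for (i in seq_len(nrow(ev)))
      acc[rows[i], bins[i]] <- acc[rows[i], bins[i]] + 1
  }
  acc <- acc / length(maps)
  if (by_type) acc else colSums(acc)
}

.as_map_list <- function(maps) {
  if (inherits(maps, "simmap_set")) {
    live <- setdiff(seq_along(maps$trees), maps$skipped)
    maps <- unlist(maps$maps[live], recursive = FALSE)
  }
  if (inherits(maps, "stoch_map")) maps <- list(maps)
  if (!length(maps)) stop("empty map list", call. = FALSE)
  maps
}

#' Branch-length-normalized transition series through time
#'
#' The rate-through-time statistic: per ordered transition type and time
#' bin, the mean event count over maps divided by the total branch length in
#' the bin (events per Myr of lineage). Bins containing no branch length are
#' undefined (NA), not zero. A `"total"` series (sum over the six types) is
#' appended.
#'
#' @param maps a `"simmap_set"` or list of `"stoch_map"`s on `tree`.
#' @param tree the (ultrametric) tree the maps were drawn on.
#' @param B number of time bins.
#' @return object of class `"rtt_series"`: long-format data.frame with
#'   columns `type`, `bin`, `older`, `younger`, `value`,
#'   `branch_length_myr`, `mean_count`; attributes `grid` and `n_maps`.
#' @export
normalized_transition_series <- function(maps, tree, B = 50) {
  grid <- make_time_bins(tree, B)
  bl <- branch_length_per_bin(tree, grid)
  counts <- transitions_per_bin(maps, grid, by_type = TRUE)
  counts <- rbind(counts, total = colSums(counts))
  value <- sweep(counts, 2, bl, "/")
  value[, bl == 0] <- NA_real_
  n_maps <- length(.as_map_list(maps))
  out <- data.frame(
    type = rep(rownames(counts), each = grid$B),
    bin = rep(seq_len(grid$B), times = nrow(counts)),
    older = rep(grid$edges[-(grid$B + 1)], times = nrow(counts)),
    younger = rep(grid$edges[-1], times = nrow(counts)),
    value = as.vector(t(value)),
    branch_length_myr = rep(bl, times = nrow(counts)),
    mean_count = as.vector(t(counts)),
    stringsAsFactors = FALSE)
  structure(out, class = c("rtt_series", "data.frame"),
            grid = grid, n_maps = n_maps)
}

#' Align per-tree transition series on a common absolute-age axis
#'
#' Re-expresses a list of per-tree series (each binned over its own root
#' age) on a shared grid anchored at the present and spanning the oldest
#' root age, by piecewise-constant lookup at common-bin midpoints. Bins
#' older than a tree's root are undefined for that tree. Per-tree curves are
#' retained; a pointwise median curve per type is attached.
#'
#' @param series_list list of `"rtt_series"` objects with a common `B`.
#' @return object of class `"rtt_bundle"`: list with `curves` (long
#'   data.frame: `tree`, `type`, `bin`, `older`, `younger`, `value`),
#'   `median` (data.frame per type and bin) and `edges`.
#' @export
aggregate_over_posterior <- function(series_list) {
  if (!length(series_list)) stop("need at least one series", call. = FALSE)
  Bs <- vapply(series_list, function(s) attr(s, "grid")$B, integer(1))
  if (length(unique(Bs)) != 1L)
    stop("mixed bin counts across trees: ", paste(unique(Bs), collapse = ", "),
         call. = FALSE)
  B <- Bs[1]
  roots <- vapply(series_list, function(s) attr(s, "grid")$root_age, numeric(1))
  span <- max(roots)
  edges <- seq(span, 0, length.out = B + 1)
  mids <- (edges[-1] + edges[-(B + 1)]) / 2
  types <- unique(series_list[[1]]$type)
  rows <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    g <- attr(s, "grid")
    bin_idx <- ifelse(mids > g$root_age, NA_integer_, .bin_of(mids, g))
    for (ty in types) {
      v <- s$value[s$type == ty][bin_idx]
      rows[[length(rows) + 1L]] <- data.frame(
        tree = i, type = ty, bin = seq_len(B),
        older = edges[-(B + 1)], younger = edges[-1], value = v,
        stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, rows)
  med <- stats::aggregate(value ~ type + bin, data = curves, FUN = stats::median,
                          na.action = stats::na.pass)
  med <- med[order(med$type, med$bin), ]
  structure(list(curves = curves, median = med, edges = edges),
            class = "rtt_bundle")
}
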