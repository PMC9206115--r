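#' Catalog of the 10 morphological wave-pattern features
#'
#' The fixed vocabulary used to score cortical wave movies: flickers,
#' pulse-mediated turbulence, fully developed and spatially localized
#' spiral turbulence, lamellar wave trains, wave-front dislocations, grain
#' boundaries, single- and two-armed spirals, and line defects.  Scoring is
#' human (presence/absence per movie); this module only encodes the
#' vocabulary and the histogram arithmetic.
#'
#' @return Data frame with columns `id` (1-10), `name`, `definition`.
#' @export
feature_catalog <- function() {
  data.frame(
    id = 1:10,
    name = c("rho_flickers", "pulse_mediated_turbulence",
             "spiral_turbulence_full", "spiral_turbulence_localized",
             "lamellar_wave_trains", "wavefront_dislocations",
             "grain_boundaries", "single_armed_spirals",
             "two_armed_spirals", "line_defects"),
    definition = c(
      "spatially disorganized local flashes of activity, no propagation",
      "isolated activity maxima that erratically move a short distance before disappearing",
      "well-formed wave fragments densely populating the field of view; temporal but not spatial correlation",
      "turbulent dynamics confined to limited areas surrounded by organized wave trains and spirals",
      "persistent domains of flat or slightly curved waves with robust propagation",
      "dislocations of wave fronts",
      "interface pattern between two wave trains with near-orthogonal wave vectors",
      "well-formed single-armed spiral waves with >= 2-3 full turns",
      "stable two-armed spiral waves with >= 2-3 full turns",
      "boundaries between wave trains with nearly antiparallel wave vectors"))
}

#' Binary feature score table
#'
#' One row per experimental movie: a group label (e.g. the injected GAP
#' mRNA dose) and the ten 0/1 presence scores `f1`...`f10`.
#'
#' @param group character or factor vector of group labels.
#' @param scores matrix or data frame of 0/1 entries with 10 columns.
#' @return An object of class `cw_score_table` (a data frame).
#' @export
cw_score_table <- function(group, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 10) stop("score table must have exactly 10 features")
  if (length(group) != nrow(scores))
    stop("one group label per experiment row is required")
  if (!all(scores %in% c(0, 1))) stop("scores must be binary 0/1")
  out <- data.frame(group = as.character(group), scores)
  names(out)[-1] <- paste0("f", 1:10)
  class(out) <- c("cw_score_table", "data.frame")
  out
}

#' Read a feature score table from CSV
#'
#' Expects columns `group, f1...f10`.
#'
#' @param path CSV path.
#' @return A [cw_score_table()].
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", paste0("f", 1:10))
  if (!all(need %in% names(df)))
    stop("score CSV must have columns: ", paste(need, collapse = ", "))
  cw_score_table(df$group, df[paste0("f", 1:10)])
}

#' Relative-frequency histogram of morphological features
#'
#' For each (group, feature) cell, the sum of 0/1 scores is divided by a
#' normalizing total.  The literal reading of the published procedure
#' (`normalize = "grand"`, default) divides by the grand total of all
#' occurrences across all experiments, so the whole matrix sums to 1; the
#' conventional per-group variant (`normalize = "group"`) divides each row
#' by that group's occurrence total, so each row sums to 1.
#'
#' @param table a [cw_score_table()].
#' @param normalize `"grand"` or `"group"`.
#' @return Matrix `H[group, feature]` of relative frequencies, groups in
#'   first-appearance order.
#' @export
feature_histogram <- function(table, normalize = c("grand", "group")) {
  stopifnot(inherits(table, "cw_score_table"))
  normalize <- match.arg(normalize)
  groups <- unique(table$group)
  counts <- t(vapply(groups, function(g)
    colSums(table[table$group == g, paste0("f", 1:10), drop = FALSE]),
    numeric(10)))
  rownames(counts) <- groups
  grand <- sum(counts)
  if (grand == 0) stop("all-zero score table: nothing to normalize")
  if (normalize == "grand") counts / grand
  else sweep(counts, 1, pmax(rowSums(counts), 1), "/")
}

#' Group sizes of a score table
#'
#' @param table a [cw_score_table()].
#' @return List with `per_group` (named integer vector, first-appearance
#'   order) and `total`.
#' @export
group_sizes <- function(table) {
  stopifnot(inherits(table, "cw_score_table"))
  groups <- unique(table$group)
  per <- vapply(groups, function(g) sum(table$group == g), 0L)
  list(per_group = per, total = sum(per))
}
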