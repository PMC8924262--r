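# Synthetic per-cell responder and neurite tables.
#
# Each group is described by a row of a spec table: number of cells, the
# probability of responding to stretch, the probability of bearing at least
# one neurite, the log-normal parameters of the longest-neurite length and
# the Poisson rate of the neurite count (zero-truncated for bearing cells).

#' Default group specifications for the cell-table generator
#'
#' Group sizes and rates mirror the stretch-responder and neurite-outgrowth
#' experiments: responder groups with their tested-cell counts and observed
#' responder fractions, and neurite groups with their cell counts,
#' neurite-bearing fractions and mean longest-neurite lengths.
#'
#' @return A tibble with columns `group`, `n_cells`, `p_responder`,
#'   `p_bearing`, `neurite_mean_um`, `neurite_sd_log`, `count_lambda`.
#' @export
default_cell_groups <- function() {
  tibble(
    group = c("PIEZO2", "IDR1del", "IDR4del", "IDR5del",
              "GFP_control", "GFP_NGF", "PIEZO2_NGF", "IDR5del_NGF"),
    n_cells = c(38, 19, 42, 22, 836, 854, 998, 810),
    p_responder = c(8 / 38, 9 / 19, 25 / 42, 10 / 22, NA, NA, NA, NA),
    p_bearing = c(NA, NA, NA, NA, 0.41, 0.87, 0.73, 0.84),
    neurite_mean_um = c(NA, NA, NA, NA, 13.6, 28.7, 17.4, 26.3),
    neurite_sd_log = c(NA, NA, NA, NA, 0.6, 0.6, 0.6, 0.6),
    count_lambda = c(NA, NA, NA, NA, 1.2, 2.5, 1.8, 2.4))
}

# zero-truncated Poisson sampler via inverse CDF
rztpois <- function(n, lambda) {
  u <- runif(n, ppois(0, lambda), 1)
  qpois(u, lambda)
}

#' Simulate per-cell responder and neurite tables
#'
#' @param groups Spec tibble as in [default_cell_groups()]; `p_responder`
#'   and/or the neurite columns may be `NA` for groups not used in the
#'   corresponding assay.
#' @param seed Integer seed for bit-reproducibility.
#' @return Tibble with one row per cell: `group`, `cell_id`, `responder`,
#'   `neurite_bearing`, `longest_neurite_um`, `n_neurites`.
#' @export
simulate_cell_tables <- function(groups = default_cell_groups(), seed = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_cells") %in% names(groups)))
  probs <- c(groups$p_responder, groups$p_bearing)
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    abort("probabilities must lie in [0, 1].")
  }
  local_seed(seed)
  purrr::pmap_dfr(groups, function(group, n_cells, p_responder = NA,
                                   p_bearing = NA, neurite_mean_um = NA,
                                   neurite_sd_log = NA, count_lambda = NA,
                                   ...) {
    responder <- if (is.na(p_responder)) rep(NA, n_cells)
                 else rbinom(n_cells, 1, p_responder) == 1
    if (is.na(p_bearing)) {
      bearing <- rep(NA, n_cells)
      longest <- rep(NA_real_, n_cells)
      counts <- rep(NA_integer_, n_cells)
    } else {
      bearing <- rbinom(n_cells, 1, p_bearing) == 1
      sdl <- neurite_sd_log
      mu <- log(neurite_mean_um) - sdl^2 / 2    # log-normal with given mean
      longest <- ifelse(bearing, rlnorm(n_cells, mu, sdl), 0)
      counts <- ifelse(bearing, rztpois(n_cells, count_lambda), 0L)
    }
    tibble(group = group, cell_id = seq_len(n_cells), responder = responder,
           neurite_bearing = bearing, longest_neurite_um = longest,
           n_neurites = as.integer(counts))
  })
}

#' Collapse a cell table into a 2x2 responder table
#'
#' @param cells A table from [simulate_cell_tables()] (or real data with the
#'   same columns).
#' @param group1,group2 Group labels to contrast.
#' @return A 2x2 integer matrix (rows = groups, columns = responder /
#'   non-responder), suitable for [fisher_exact_2x2()].
#' @export
responder_table <- function(cells, group1, group2) {
  cnt <- function(g) {
    r <- cells$responder[cells$group == g]
    r <- r[!is.na(r)]
    c(sum(r), sum(!r))
  }
  m <- rbind(cnt(group1), cnt(group2))
  dimnames(m) <- list(c(group1, group2), c("responder", "non_responder"))
  storage.mode(m) <- "integer"
  m
}
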