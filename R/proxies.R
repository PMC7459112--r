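#' Rank flux values within one campaign
#'
#' Ascending ranks (1 = smallest) among the non-missing values of a campaign;
#' missing values stay missing and do not consume ranks. Ties are handled by
#' the chosen rule (`"average"` assigns tied values the mean of their rank
#' span).
#'
#' @param values Numeric vector of flux values for one campaign.
#' @param ties `"average"`, `"min"` or `"ordinal"` (first occurrence wins).
#' @return Numeric vector of ranks, same length as `values`.
#' @examples
#' rank_campaign(c(2.0, 0.5, 1.1))   # 3 1 2
#' rank_campaign(c(1, 1, 2))         # 1.5 1.5 3
#' @export
rank_campaign <- function(values, ties = c("average", "min", "ordinal")) {
  ties <- match.arg(ties)
  if (all(is.na(values))) {
    stop("Cannot rank a campaign with no observed values.", call. = FALSE)
  }
  method <- switch(ties, average = "average", min = "min", ordinal = "first")
  rank(values, na.last = "keep", ties.method = method)
}

# positions x campaigns matrix of a panel variable, rows ordered by first
# appearance of position_id, columns by campaign number.
panel_matrix <- function(panel, var) {
  stopifnot(all(c("position_id", "campaign", var) %in% names(panel)))
  pos <- unique(panel$position_id)
  camps <- sort(unique(panel$campaign))
  m <- matrix(NA_real_, length(pos), length(camps),
              dimnames = list(pos, camps))
  m[cbind(match(panel$position_id, pos), match(panel$campaign, camps))] <-
    panel[[var]]
  m
}

# within-campaign rank matrix of rs
rank_matrix <- function(panel, ties = "average") {
  m <- panel_matrix(panel, "rs")
  if (ncol(m) < 2) stop("At least 2 campaigns are required.", call. = FALSE)
  apply(m, 2L, rank_campaign, ties = ties)
}

#' Per-position stability proxies
#'
#' `compute_rank_rs()` is the temporal mean of a position's within-campaign
#' rank (rankRs): a persistent-activity proxy, large where soil respiration is
#' persistently high. `compute_range_rs()` is the max-minus-min of those ranks
#' (rangeRs): a response-amplitude proxy, 0 for a position whose rank never
#' changes (resistant), large for rank-mobile (resilient) positions. Both
#' ignore campaigns where the position is missing.
#'
#' @param panel A `campaign_panel` (long tibble with `position_id`, `campaign`,
#'   `rs`).
#' @param ties Tie rule passed to [rank_campaign()].
#' @return Tibble: `position_id` plus `rank_rs` or `range_rs`.
#' @export
compute_rank_rs <- function(panel, ties = "average") {
  rk <- rank_matrix(panel, ties)
  tibble::tibble(position_id = rownames(rk),
                 rank_rs = unname(rowMeans(rk, na.rm = TRUE))) |>
    dplyr::mutate(rank_rs = ifelse(is.nan(.data$rank_rs), NA_real_,
                                   .data$rank_rs))
}

#' @rdname compute_rank_rs
#' @export
compute_range_rs <- function(panel, ties = "average") {
  rk <- rank_matrix(panel, ties)
  rng <- apply(rk, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_real_ else max(r) - min(r)
  })
  tibble::tibble(position_id = rownames(rk), range_rs = unname(rng))
}

#' Temporal means of the background variables
#'
#' Arithmetic mean over the campaigns in which each variable was observed
#' (SOC is typically sampled in a subset of campaigns; unobserved campaigns
#' are ignored, not treated as zero).
#'
#' @param panel A `campaign_panel`.
#' @return Tibble: `position_id`, `mean_soc`, `mean_swc`.
#' @export
compute_temporal_means <- function(panel) {
  soc <- panel_matrix(panel, "soc")
  swc <- panel_matrix(panel, "swc")
  msoc <- rowMeans(soc, na.rm = TRUE)
  msoc[is.nan(msoc)] <- NA_real_
  mswc <- rowMeans(swc, na.rm = TRUE)
  mswc[is.nan(mswc)] <- NA_real_
  tibble::tibble(position_id = rownames(soc), mean_soc = unname(msoc),
                 mean_swc = unname(mswc))
}

#' Assign rank-based stability groups
#'
#' Positions are split on `mean(rank_rs) +/- sd(rank_rs)` (sample SD):
#' `S` below `mean - sd`, `L` above `mean + sd`, `M` in the closed interval
#' between (boundary values fall in `M`). With zero variance every position
#' is `M`.
#'
#' @param rank_rs Numeric vector of rankRs values.
#' @return Factor with levels `S`, `M`, `L`.
#' @export
assign_rank_groups <- function(rank_rs) {
  ok <- !is.na(rank_rs)
  if (sum(ok) < 3) stop("At least 3 positions are required.", call. = FALSE)
  m <- mean(rank_rs[ok]); s <- stats::sd(rank_rs[ok])
  out <- rep(NA_character_, length(rank_rs))
  if (is.na(s) || s == 0) {
    out[ok] <- "M"
  } else {
    out[ok] <- dplyr::case_when(
      rank_rs[ok] < m - s ~ "S",
      rank_rs[ok] > m + s ~ "L",
      TRUE ~ "M"
    )
  }
  factor(out, levels = c("S", "M", "L"))
}

#' Assign SOC quintile groups
#'
#' Positions are split into five groups `C1` (smallest mean SOC) to `C5`
#' (largest) of near-equal size: `n %/% 5` each with the remainder going to
#' the lowest groups first (78 positions give sizes 16, 16, 16, 15, 15).
#' Ties in `mean_soc` are broken by position order (stable).
#'
#' @param mean_soc Numeric vector of per-position mean SOC (%).
#' @return Factor with levels `C1`-`C5`.
#' @export
assign_soc_quintiles <- function(mean_soc) {
  ok <- which(!is.na(mean_soc))
  if (length(ok) < 5) {
    stop("At least 5 positions with mean SOC are required.", call. = FALSE)
  }
  if (length(unique(mean_soc[ok])) < 5) {
    dup <- unique(mean_soc[ok][duplicated(mean_soc[ok])])
    stop("Fewer than 5 distinct mean SOC values; duplicated values: ",
         paste(signif(dup, 6), collapse = ", "), call. = FALSE)
  }
  n <- length(ok)
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp_sorted <- rep(paste0("C", 1:5), times = sizes)
  ord <- ok[order(mean_soc[ok], ok)]
  out <- rep(NA_character_, length(mean_soc))
  out[ord] <- grp_sorted
  factor(out, levels = paste0("C", 1:5))
}

#' Compute the full per-position proxy table
#'
#' One row per measuring position: stability proxies (`rank_rs`, `range_rs`),
#' temporal means of the background variables (`mean_soc`, `mean_swc`) and the
#' subgroup labels (`rank_group` S/M/L, `soc_group` C1-C5).
#'
#' @param panel A `campaign_panel`.
#' @param ties Tie rule for ranking (see [rank_campaign()]).
#' @return A `stability_proxies` tibble.
#' @export
compute_proxies <- function(panel, ties = "average") {
  coords <- panel |>
    dplyr::distinct(.data$position_id, .keep_all = TRUE) |>
    dplyr::select("position_id", "x", "y")
  out <- coords |>
    dplyr::left_join(compute_rank_rs(panel, ties), by = "position_id") |>
    dplyr::left_join(compute_range_rs(panel, ties), by = "position_id") |>
    dplyr::left_join(compute_temporal_means(panel), by = "position_id") |>
    dplyr::mutate(
      rank_group = assign_rank_groups(.data$rank_rs),
      soc_group = assign_soc_quintiles(.data$mean_soc)
    )
  structure(out, class = c("stability_proxies", class(out)))
}
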