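#' Scale-dependent correlation scan
#'
#' Pearson correlations between every stability proxy / background variable
#' and every terrain attribute, at every pyramid level, within every subgroup:
#' `A` (all positions), the rankRs groups `S`/`M`/`L` and the SOC quintiles
#' `C1`-`C5`. Significance is the two-sided p of the linear correlation at
#' `alpha` with no multiplicity correction by default (set `adjust` for a
#' Benjamini-Hochberg variant). Subgroups smaller than 3 are skipped with a
#' warning; zero-variance pairs yield a record with `NA` correlation.
#'
#' @param proxies A [compute_proxies()] tibble.
#' @param terrain_long Long extraction from [extract_terrain()].
#' @param responses Proxy/background columns of `proxies` to scan.
#' @param levels Pyramid levels to scan (default 1-5).
#' @param alpha Significance level.
#' @param adjust P-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method), applied across the whole scan.
#' @return Tibble: `response`, `attribute`, `level`, `subgroup`, `n`, `r`,
#'   `r2`, `p`, `sign`, `significant`.
#' @export
correlation_scan <- function(proxies, terrain_long,
                             responses = c("rank_rs", "range_rs",
                                           "mean_soc", "mean_swc"),
                             levels = 1:5, alpha = 0.05, adjust = "none") {
  stopifnot(all(responses %in% names(proxies)))
  groups <- c(
    list(A = proxies$position_id),
    split(proxies$position_id, proxies$rank_group),
    split(proxies$position_id, proxies$soc_group)
  )
  terr <- dplyr::filter(terrain_long, .data$level %in% levels)
  combos <- tidyr::expand_grid(
    response = responses,
    key = dplyr::distinct(terr, .data$attribute, .data$level),
    subgroup = names(groups)
  ) |> tidyr::unpack("key")

  small <- character(0)
  rows <- purrr::pmap_dfr(combos, function(response, attribute, level, subgroup) {
    ids <- groups[[subgroup]]
    if (length(ids) < 3) {
      small <<- union(small, subgroup)
      return(NULL)
    }
    yv <- proxies[[response]][match(ids, proxies$position_id)]
    tv <- terr |>
      dplyr::filter(.data$attribute == !!attribute, .data$level == !!level,
                    .data$position_id %in% ids)
    xv <- tv$value[match(ids, tv$position_id)]
    ok <- stats::complete.cases(xv, yv)
    n <- sum(ok)
    base <- tibble::tibble(response = response, attribute = attribute,
                           level = as.integer(level), subgroup = subgroup,
                           n = n)
    if (n < 3 || stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      return(dplyr::mutate(base, r = NA_real_, r2 = NA_real_, p = NA_real_,
                           sign = NA_character_))
    }
    ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson")
    dplyr::mutate(base, r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                  p = ct$p.value,
                  sign = ifelse(ct$estimate >= 0, "pos", "neg"))
  })
  if (length(small)) {
    warning("Subgroup(s) with fewer than 3 positions skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  rows |>
    dplyr::mutate(
      p_adj = if (adjust == "none") .data$p else
        stats::p.adjust(.data$p, method = adjust),
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha
    ) |>
    dplyr::select(-"p_adj")
}

#' Classify correlations as scale-independent or smooth-scale-limited
#'
#' For every (response, attribute, subgroup) combination: `scale_independent`
#' when the correlation is significant with a consistent sign at *every*
#' level scanned (DEM1-5); `less_smooth_only` when significance is confined
#' to the least-smoothed levels ({1,2} or {1,2,3}, consistent sign);
#' otherwise `none`.
#'
#' @param records A [correlation_scan()] tibble covering `levels`.
#' @param levels Levels the classification is defined over.
#' @return Tibble: `response`, `attribute`, `subgroup`, `class`,
#'   `levels_significant` (list-column), `sign`.
#' @export
classify_scale_dependence <- function(records, levels = 1:5) {
  have <- sort(unique(records$level))
  if (!all(levels %in% have)) {
    stop("Records are missing level(s): ",
         paste(setdiff(levels, have), collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::filter(.data$level %in% levels) |>
    dplyr::group_by(.data$response, .data$attribute, .data$subgroup) |>
    dplyr::summarise(
      levels_significant = list(sort(.data$level[.data$significant])),
      consistent = {
        s <- .data$sign[.data$significant]
        length(s) > 0 && length(unique(s)) == 1
      },
      sign = if (any(.data$significant))
        unique(.data$sign[.data$significant])[1] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = purrr::map2_chr(.data$levels_significant, .data$consistent,
        function(ls, cons) {
          if (!cons) return("none")
          if (identical(ls, as.integer(levels))) return("scale_independent")
          if (identical(ls, 1:2) || identical(ls, 1:3)) return("less_smooth_only")
          "none"
        })
    ) |>
    dplyr::select("response", "attribute", "subgroup", "class",
                  "levels_significant", "sign")
}

#' Fit the Gaussian bell-curve stability model
#'
#' Fits \deqn{rangeRs = a \frac{1}{\sigma\sqrt{2\pi}}
#'   e^{-(rankRs-\mu)^2 / 2\sigma^2}}
#' linking the persistence proxy (rankRs) to the response-amplitude proxy
#' (rangeRs): rank range is largest at intermediate mean rank and small at
#' both extremes. With `fix_moments = TRUE` (default) \eqn{\mu} and
#' \eqn{\sigma} are the sample mean and SD of rankRs and the scale `a` has the
#' closed-form least-squares solution
#' \eqn{\hat a = \sum y_i g_i / \sum g_i^2} with \eqn{g_i} the Gaussian
#' density at `rank_rs[i]`. With `fix_moments = FALSE` all three parameters
#' are fit by nonlinear least squares initialized at the moment values.
#' Significance is an F test against the constant-mean model plus Wald t
#' tests per parameter.
#'
#' @param data Data frame with the proxy columns.
#' @param rank_rs,range_rs Columns (tidy-eval) holding the two proxies.
#' @param fix_moments Fix `mu`/`sigma` at the sample moments?
#' @return A `bell_fit` object; see [tidy.bell_fit()], [glance.bell_fit()],
#'   [autoplot.bell_fit()].
#' @export
fit_bell_curve <- function(data, rank_rs = rank_rs, range_rs = range_rs,
                           fix_moments = TRUE) {
  xv <- dplyr::pull(data, {{ rank_rs }})
  yv <- dplyr::pull(data, {{ range_rs }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 5) stop("At least 5 positions are required.", call. = FALSE)
  mu0 <- mean(xv); sig0 <- stats::sd(xv)
  if (is.na(sig0) || sig0 <= 0) {
    stop("rankRs has zero spread; sigma is undefined.", call. = FALSE)
  }
  degenerate <- stats::sd(yv) == 0
  if (fix_moments) {
    g <- stats::dnorm(xv, mu0, sig0)
    a <- sum(yv * g) / sum(g^2)
    mu <- mu0; sigma <- sig0
    n_par <- 1L
  } else {
    fit <- minpack.lm::nlsLM(
      yv ~ a * stats::dnorm(xv, mu, sigma),
      start = list(a = sum(yv * stats::dnorm(xv, mu0, sig0)) /
                     sum(stats::dnorm(xv, mu0, sig0)^2),
                   mu = mu0, sigma = sig0),
      lower = c(a = -Inf, mu = -Inf, sigma = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); mu <- unname(cf["mu"]); sigma <- unname(cf["sigma"])
    n_par <- 3L
  }
  fitted <- a * stats::dnorm(xv, mu, sigma)
  rss <- sum((yv - fitted)^2)
  ss0 <- sum((yv - mean(yv))^2)
  df2 <- n - n_par - 1L
  fstat <- if (rss > 0 && df2 > 0) ((ss0 - rss) / n_par) / (rss / df2) else Inf
  f_p <- if (is.finite(fstat)) stats::pf(fstat, n_par, df2, lower.tail = FALSE)
         else 0
  sigma_res <- sqrt(rss / max(n - n_par, 1))
  g <- stats::dnorm(xv, mu, sigma)
  se_a <- sigma_res / sqrt(sum(g^2))
  t_a <- a / se_a
  p_a <- 2 * stats::pt(abs(t_a), df = max(n - n_par, 1), lower.tail = FALSE)
  structure(
    list(a = a, mu = mu, sigma = sigma, fix_moments = fix_moments,
         n = n, rss = rss, ss_tot = ss0,
         r_squared = if (ss0 > 0) 1 - rss / ss0 else NA_real_,
         f_statistic = fstat, f_df = c(n_par, df2), f_p_value = f_p,
         se_a = se_a, t_a = t_a, p_a = p_a,
         degenerate = degenerate,
         data = tibble::tibble(rank_rs = xv, range_rs = yv, fitted = fitted)),
    class = "bell_fit"
  )
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf(
    "<bell_fit> rangeRs = a * N(rankRs; mu, sigma)%s\n  a = %.2f (SE %.2f), mu = %.2f, sigma = %.2f, n = %d\n  R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
    if (x$fix_moments) " [moments fixed]" else "",
    x$a, x$se_a, x$mu, x$sigma, x$n, x$r_squared,
    x$f_df[1], x$f_df[2], x$f_statistic, x$f_p_value))
  if (x$degenerate) cat("  note: rangeRs is constant (degenerate fit)\n")
  invisible(x)
}

#' Tidy a bell-curve fit
#'
#' @param x A `bell_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (Wald columns only for the free scale parameter).
#' @exportS3Method generics::tidy
tidy.bell_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "mu", "sigma"),
    estimate = c(x$a, x$mu, x$sigma),
    std.error = c(x$se_a, NA_real_, NA_real_),
    statistic = c(x$t_a, NA_real_, NA_real_),
    p.value = c(x$p_a, NA_real_, NA_real_)
  )
}

#' @rdname tidy.bell_fit
#' @return `glance()` returns a one-row model summary.
#' @exportS3Method generics::glance
glance.bell_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma = sqrt(x$rss / max(x$n - x$f_df[1], 1)),
    statistic = x$f_statistic, p.value = x$f_p_value,
    df = x$f_df[1], df.residual = x$f_df[2], nobs = x$n
  )
}

#' @rdname tidy.bell_fit
#' @return `augment()` returns the data with `.fitted` and `.resid`.
#' @exportS3Method generics::augment
augment.bell_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = .data$fitted,
                .resid = .data$range_rs - .data$fitted) |>
    dplyr::select(-"fitted")
}

#' Two-state equilibrium classification
#'
#' Operationalizes the two-state reading of the proxy space through the
#' rank-based subgroups: positions with large mean rank (`L`, persistently
#' high activity — expected at low elevation with high SOC/SWC) are state
#' `I`; positions with small mean rank (`S`, persistently low activity —
#' expected on local ridges) are state `II`; the middle (`M`) positions are
#' `intermediate`, the resilient majority with the largest rank ranges.
#'
#' @param proxies A [compute_proxies()] tibble (needs `rank_group`).
#' @return The proxies tibble with a `state` factor
#'   (`I`, `II`, `intermediate`).
#' @export
classify_states <- function(proxies) {
  stopifnot("rank_group" %in% names(proxies))
  dplyr::mutate(proxies, state = factor(
    dplyr::case_when(
      .data$rank_group == "L" ~ "I",
      .data$rank_group == "S" ~ "II",
      TRUE ~ "intermediate"
    ),
    levels = c("I", "II", "intermediate")
  ))
}

#' Per-state summaries of proxies and terrain
#'
#' Mean proxy values and (optionally) mean terrain attributes per equilibrium
#' state, for the narrative comparison of the two resistant states against
#' the resilient middle.
#'
#' @param states Output of [classify_states()].
#' @param terrain_long Optional [extract_terrain()] table; attribute means are
#'   computed at `level`.
#' @param level Pyramid level used for terrain summaries.
#' @return One row per state.
#' @export
summarise_states <- function(states, terrain_long = NULL, level = 1) {
  base <- states |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      rank_rs = mean(.data$rank_rs, na.rm = TRUE),
      range_rs = mean(.data$range_rs, na.rm = TRUE),
      mean_soc = mean(.data$mean_soc, na.rm = TRUE),
      mean_swc = mean(.data$mean_swc, na.rm = TRUE),
      .groups = "drop"
    )
  if (is.null(terrain_long)) return(base)
  terr <- terrain_long |>
    dplyr::filter(.data$level == !!level) |>
    dplyr::left_join(dplyr::select(states, "position_id", "state"),
                     by = "position_id") |>
    dplyr::group_by(.data$state, .data$attribute) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "attribute", values_from = "value")
  dplyr::left_join(base, terr, by = "state")
}

#' Study-period meteorology table
#'
#' Yearly mean air temperature (deg C), precipitation sum (mm) and net
#' ecosystem exchange (g C m-2 yr-1) for the seven study years at the
#' grassland site, plus the long-term reference precipitation.
#'
#' @return Tibble: `year`, `tair`, `precip`, `nee`.
#' @export
site_meteorology <- function() {
  tibble::tibble(
    year = 2012:2018,
    tair = c(10.7, 10.8, 11.4, 11.2, 10.6, 10.7, 11.7),
    precip = c(431, 590, 813, 523, 584, 654, 578),
    nee = c(37.9, -63.5, -38.4, -79.8, -79.5, -49.8, -39.1)
  )
}

#' Percentage deviation of annual precipitation from a reference mean
#'
#' Rounded to the nearest integer percent: the 813 mm wettest study year
#' against the 585 mm long-term mean gives +39.
#'
#' @param year_mm Annual precipitation sum (mm).
#' @param reference_mm Long-term mean annual precipitation (mm, default the
#'   site's fifteen-year mean of 585).
#' @return Integer percent deviation (positive = wetter than the reference).
#' @export
precip_deviation <- function(year_mm, reference_mm = 585) {
  if (any(reference_mm <= 0)) stop("`reference_mm` must be positive.", call. = FALSE)
  as.integer(round(100 * (year_mm - reference_mm) / reference_mm))
}
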