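#' Phenotypic Plasticity Index of a monthly mean series
#'
#' The PPI measures the amplitude of a plastic response from the extreme
#' *population* means observed over the study:
#' `PPI = 100 * (max mean - min mean) / max mean` (% of change). It uses
#' monthly means only — never per-individual extremes.
#'
#' @param monthly_means Numeric vector of monthly population means, all
#'   positive, length >= 2.
#' @return One-row tibble: `max_mean`, `min_mean`, `ppi_pct` (in \[0, 100)),
#'   `n_months`.
#' @examples
#' ppi(c(82.2, 77.6, 48.8))  # ppi_pct ~ 40.6
#' @export
ppi <- function(monthly_means) {
  monthly_means <- monthly_means[!is.na(monthly_means)]
  if (length(monthly_means) < 2) {
    stop_input("PPI needs at least 2 monthly means")
  }
  if (any(monthly_means <= 0)) {
    stop_input("PPI is defined for positive-valued traits only")
  }
  mx <- max(monthly_means); mn <- min(monthly_means)
  tibble::tibble(max_mean = mx, min_mean = mn,
                 ppi_pct = 100 * (mx - mn) / mx,
                 n_months = length(monthly_means))
}

#' Intensity of thermal plasticity
#'
#' Percentage of trait change per degree Celsius, `PPI / TAR`, a proxy for
#' how sensitive the plastic response is to the local temperature range.
#'
#' @param ppi_pct PPI (%), >= 0.
#' @param tar_c Temperature annual range (degC), > 0.
#' @return Intensity (%/degC), vectorised.
#' @export
plasticity_intensity <- function(ppi_pct, tar_c) {
  if (any(tar_c <= 0, na.rm = TRUE)) {
    stop_degenerate("intensity is undefined for TAR <= 0")
  }
  ppi_pct / tar_c
}

#' Reaction norm of a population trait along an environmental gradient
#'
#' Pairs monthly trait means with monthly environment means (months missing
#' either side are dropped), screens both vectors for normality
#' (Shapiro-Wilk at `alpha_normality`), and classifies the trait as plastic
#' when the correlation is significant at `alpha`. When the screen fails,
#' a log10 transform is tried once (only if all values are positive); if
#' normality still fails, a Spearman rank-order correlation is used.
#'
#' @param trait_means Numeric vector of monthly trait means.
#' @param env_means Numeric vector of monthly environment means, same
#'   length/order as `trait_means`.
#' @param trait,env Labels recorded in the result.
#' @param alpha Significance level for the plasticity call (default 0.05).
#' @param alpha_normality Shapiro-Wilk level for the normality screen.
#' @return One-row tibble: `trait`, `env`, `method` (`"pearson"`,
#'   `"pearson_log"` or `"spearman"`), `r`, `p`, `n`, `plastic`.
#' @export
reaction_norm <- function(trait_means, env_means, trait = "trait",
                          env = "env", alpha = 0.05,
                          alpha_normality = 0.05) {
  ok <- !is.na(trait_means) & !is.na(env_means)
  x <- env_means[ok]; y <- trait_means[ok]
  if (length(x) < 3) {
    stop_input("fewer than 3 paired months for reaction norm %s ~ %s",
               trait, env)
  }
  normal_enough <- function(v) {
    length(unique(v)) > 1 && shapiro.test(v)$p.value > alpha_normality
  }
  method <- NULL
  if (normal_enough(x) && normal_enough(y)) {
    res <- pearson_r(x, y)
    method <- "pearson"
  } else if (all(x > 0) && all(y > 0) &&
             normal_enough(log10(x)) && normal_enough(log10(y))) {
    res <- pearson_r(log10(x), log10(y))
    method <- "pearson_log"
  } else {
    s <- spearman_rho(x, y)
    res <- tibble::tibble(r = s$rho, p = s$p, n = s$n)
    method <- "spearman"
  }
  tibble::tibble(trait = trait, env = env, method = method,
                 r = res$r, p = res$p, n = res$n,
                 plastic = res$p <= alpha)
}

#' Reaction norms for every trait x environment combination
#'
#' Convenience wrapper joining the long monthly trait table from
#' [monthly_trait_means()] with a monthly environment table and running
#' [reaction_norm()] for each trait against each environmental variable.
#' No multiple-testing correction is applied across the grid; the `p`
#' column is the per-test probability.
#'
#' @param trait_means Long tibble from [monthly_trait_means()]
#'   (`month`, `trait`, `mean`).
#' @param environment Tibble with `month` and one column per environmental
#'   variable (e.g. `mean_temperature`, `phyto_biomass_mgl`).
#' @param env_vars Environment columns to test (default: all numeric
#'   columns except `month`).
#' @param alpha Passed to [reaction_norm()].
#' @return Tibble with one row per trait x environment pair.
#' @export
reaction_norm_grid <- function(trait_means, environment,
                               env_vars = NULL, alpha = 0.05) {
  check_columns(trait_means, c("month", "trait", "mean"), "trait_means")
  check_columns(environment, "month", "environment")
  if (is.null(env_vars)) {
    env_vars <- names(environment)[vapply(environment, is.numeric,
                                          logical(1))]
    env_vars <- setdiff(env_vars, "month")
  }
  wide <- trait_means |>
    dplyr::select("month", "trait", "mean") |>
    dplyr::inner_join(environment, by = "month")
  combos <- tidyr::expand_grid(trait_ = unique(wide$trait), env_ = env_vars)
  purrr::pmap_dfr(combos, function(trait_, env_) {
    d <- dplyr::filter(wide, .data$trait == trait_)
    reaction_norm(d$mean, d[[env_]], trait = trait_, env = env_,
                  alpha = alpha)
  })
}

#' Plasticity amplitude table for every trait
#'
#' Computes the PPI of each trait's monthly mean series and, when a
#' temperature annual range is supplied, the per-degree intensity.
#'
#' @param trait_means Long tibble from [monthly_trait_means()].
#' @param tar_c Optional temperature annual range (degC) for the intensity
#'   column.
#' @return Tibble: `trait`, `max_mean`, `min_mean`, `ppi_pct`, `n_months`,
#'   and `intensity_pct_per_c` when `tar_c` is given.
#' @export
plasticity_table <- function(trait_means, tar_c = NULL) {
  check_columns(trait_means, c("month", "trait", "mean"), "trait_means")
  out <- trait_means |>
    dplyr::group_by(trait = .data$trait) |>
    dplyr::group_modify(~ ppi(.x$mean)) |>
    dplyr::ungroup()
  if (!is.null(tar_c)) {
    out$intensity_pct_per_c <- plasticity_intensity(out$ppi_pct, tar_c)
  }
  out
}
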