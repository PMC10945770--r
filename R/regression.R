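#' Ordinary least-squares fit of a trait on molecular distance
#'
#' Fits `y = intercept + slope * x` by OLS, dropping incomplete pairs. In the
#' directional-selection analysis `x` is the root-to-tip distance
#' (substitutions per site) and `y` a kinetic or photosynthetic trait; a
#' positive, significant slope indicates sustained change in the trait with
#' accumulating sequence evolution, and the intercept estimates the trait
#' value of the clade's last common ancestor (zero distance).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @return List of class `"evo_ols"`: `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `r_squared`, `p_slope` (two-sided t test on the slope,
#'   `n - 2` df), `n`. A constant `y` yields slope 0 and `r_squared` 0 with
#'   `p_slope = NA`.
#' @examples
#' fit_ols(c(0, 1, 2), c(1, 3, 5)) # slope 2, intercept 1, r^2 = 1
#' @export
fit_ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  # zero-noise fits are legitimate here; silence summary.lm's perfect-fit note
  co <- suppressWarnings(summary(fit))$coefficients
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  if (sst == 0) {
    res <- list(slope = 0, intercept = mean(y), se_slope = 0, se_intercept = 0,
                r_squared = 0, p_slope = NA_real_, n = n)
  } else {
    t_slope <- co["x", "Estimate"] / co["x", "Std. Error"]
    res <- list(slope = unname(co["x", "Estimate"]),
                intercept = unname(co["(Intercept)", "Estimate"]),
                se_slope = unname(co["x", "Std. Error"]),
                se_intercept = unname(co["(Intercept)", "Std. Error"]),
                r_squared = 1 - sse / sst,
                p_slope = 2 * stats::pt(abs(t_slope), df = n - 2L, lower.tail = FALSE),
                n = n)
  }
  structure(res, class = "evo_ols")
}

#' @export
print.evo_ols <- function(x, ...) {
  cat(sprintf("OLS (n = %d): slope %.4g ± %.3g, intercept %.4g ± %.3g, r² = %.3f, p = %.3g\n",
              x$n, x$slope, x$se_slope, x$intercept, x$se_intercept,
              x$r_squared, x$p_slope))
  invisible(x)
}

#' Ancestral trait value from a regression intercept
#'
#' The fitted intercept is the predicted trait value at zero root-to-tip
#' distance, i.e. for the last common ancestor at the root of the clade;
#' its standard error quantifies the uncertainty (mean ± 1 SE convention).
#'
#' @param reg An [fit_ols()] result.
#' @return Named numeric vector `c(value, se)`.
#' @export
ancestral_trait <- function(reg) {
  stopifnot(inherits(reg, "evo_ols"))
  c(value = reg$intercept, se = reg$se_intercept)
}

#' Million years per substitution
#'
#' Converts a mean root-to-tip distance (substitutions per site) into the
#' average waiting time between single substitutions, given the alignment
#' length and the age of the clade: `clade_age / (mean_rtt * n_sites)`.
#'
#' @param mean_rtt Mean root-to-tip distance, substitutions per site.
#' @param n_sites Number of aligned sites.
#' @param clade_age Age of the clade's radiation in million years (default
#'   160, the estimated age of the angiosperms).
#' @return My per substitution (numeric scalar).
#' @export
substitution_interval <- function(mean_rtt, n_sites, clade_age = 160) {
  if (!is.finite(mean_rtt) || mean_rtt <= 0) stop("mean_rtt must be positive")
  if (!is.finite(n_sites) || n_sites <= 0) stop("n_sites must be positive")
  if (!is.finite(clade_age) || clade_age <= 0) stop("clade_age must be positive")
  clade_age / (mean_rtt * n_sites)
}

#' Trait change per single substitution
#'
#' Regression slopes are in trait units per (substitutions per site);
#' dividing by the number of sites converts to trait units per single
#' substitution.
#'
#' @param slope OLS slope, trait units per substitutions-per-site.
#' @param n_sites Number of aligned sites.
#' @return Trait units per substitution.
#' @export
per_substitution_change <- function(slope, n_sites) {
  if (!is.finite(n_sites) || n_sites <= 0) stop("n_sites must be positive")
  slope / n_sites
}

#' Relative trait improvement per substitution
#'
#' Per-substitution change expressed as a percentage of the ancestral trait
#' value: `100 * per_sub_change / ancestral_value`.
#'
#' @param per_sub_change Trait change per substitution.
#' @param ancestral_value Ancestral trait value (regression intercept);
#'   must be nonzero.
#' @return Percentage (numeric scalar).
#' @export
relative_improvement <- function(per_sub_change, ancestral_value) {
  if (!is.finite(ancestral_value) || ancestral_value == 0) {
    stop("ancestral value must be nonzero")
  }
  100 * per_sub_change / ancestral_value
}

#' Relative trait improvement per million years
#'
#' Divides the (unrounded) per-substitution relative improvement by the
#' substitution interval in My.
#'
#' @param relative_per_substitution Percent improvement per substitution.
#' @param my_per_substitution My per substitution (positive).
#' @return Percent per My.
#' @export
improvement_per_my <- function(relative_per_substitution, my_per_substitution) {
  if (!is.finite(my_per_substitution) || my_per_substitution <= 0) {
    stop("my_per_substitution must be positive")
  }
  relative_per_substitution / my_per_substitution
}

#' Full improvement-rate conversion for one trait
#'
#' Chains [per_substitution_change()], [relative_improvement()],
#' [substitution_interval()] and [improvement_per_my()] from a fitted slope
#' and intercept.
#'
#' @param slope,intercept OLS slope and intercept for the trait.
#' @param mean_rtt Mean root-to-tip distance of the analysed species.
#' @param n_sites Number of aligned sites.
#' @param clade_age Clade age in My (default 160).
#' @return One-row data frame: `per_substitution_change`,
#'   `relative_per_substitution` (%), `my_per_substitution`,
#'   `relative_per_my` (%/My), `n_sites`, `clade_age`.
#' @export
improvement_rates <- function(slope, intercept, mean_rtt, n_sites, clade_age = 160) {
  per_sub <- per_substitution_change(slope, n_sites)
  rel_sub <- relative_improvement(per_sub, intercept)
  my_sub <- substitution_interval(mean_rtt, n_sites, clade_age)
  data.frame(per_substitution_change = per_sub,
             relative_per_substitution = rel_sub,
             my_per_substitution = my_sub,
             relative_per_my = improvement_per_my(rel_sub, my_sub),
             n_sites = n_sites,
             clade_age = clade_age)
}

# derived trait columns, computed only when absent and parents are present
derive_trait_columns <- function(tr) {
  if (!"kcatC_KC" %in% names(tr) && all(c("kcatC", "K_C") %in% names(tr))) {
    tr$kcatC_KC <- tr$kcatC / tr$K_C
  }
  if (!"KC_KO" %in% names(tr) && all(c("K_C", "K_O") %in% names(tr))) {
    tr$KC_KO <- tr$K_C / tr$K_O
  }
  if (!"PNUE_mass" %in% names(tr) && all(c("A_mass", "N_mass") %in% names(tr))) {
    tr$PNUE_mass <- tr$A_mass / tr$N_mass
  }
  if (!"PNUE_area" %in% names(tr) && all(c("A_area", "N_area") %in% names(tr))) {
    tr$PNUE_area <- tr$A_area / tr$N_area
  }
  tr
}

#' One trait-on-distance regression per trait
#'
#' Joins a per-species distance table with a trait table and fits one OLS
#' per trait on pairwise-complete cases (each trait keeps its own n).
#' Standard derived traits (`kcatC_KC = kcatC / K_C`, `KC_KO = K_C / K_O`,
#' `PNUE_mass = A_mass / N_mass`, `PNUE_area = A_area / N_area`) are computed
#' on the fly when absent.
#'
#' @param distances Named numeric vector (species -> root-to-tip distance) or
#'   a data frame with columns `species`, `distance`.
#' @param traits Data frame with a `species` column and numeric trait
#'   columns.
#' @param trait_names Traits to analyse; default all numeric columns.
#' @return Data frame with one row per trait: `trait`, `n`, `slope`,
#'   `se_slope`, `intercept`, `se_intercept`, `r2_percent`, `p_slope`.
#' @export
run_trait_regressions <- function(distances, traits, trait_names = NULL) {
  if (is.data.frame(distances)) {
    if (!all(c("species", "distance") %in% names(distances))) {
      stop("distance data frame needs columns 'species' and 'distance'")
    }
    d <- distances$distance
    names(d) <- as.character(distances$species)
    distances <- d
  }
  if (!"species" %in% names(traits)) stop("trait table needs a 'species' column")
  traits <- derive_trait_columns(traits)
  numeric_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  if (is.null(trait_names)) trait_names <- numeric_cols
  absent <- setdiff(trait_names, names(traits))
  if (length(absent) > 0) {
    stop("trait(s) not in table: ", paste(absent, collapse = ", "),
         "; available: ", paste(numeric_cols, collapse = ", "))
  }
  common <- intersect(names(distances), as.character(traits$species))
  x_all <- distances[match(traits$species, names(distances))]
  rows <- lapply(trait_names, function(tn) {
    fit <- tryCatch(fit_ols(x_all, traits[[tn]]),
                    error = function(e) stop("trait '", tn, "': ",
                                             conditionMessage(e), call. = FALSE))
    data.frame(trait = tn, n = fit$n, slope = fit$slope,
               se_slope = fit$se_slope, intercept = fit$intercept,
               se_intercept = fit$se_intercept,
               r2_percent = 100 * fit$r_squared, p_slope = fit$p_slope)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_species_joined") <- length(common)
  rownames(out) <- NULL
  out
}
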