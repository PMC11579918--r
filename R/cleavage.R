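#' Cleavage efficiency from band intensities
#'
#' `cleaved * 100 / (cleaved + full_length)`, the fraction of processed
#' product on a pulse-labeling autoradiograph. Densitometry units are
#' arbitrary, so the result is invariant to rescaling both intensities.
#'
#' @param cleaved,full_length Non-negative band intensities (vectorized); not
#'   both zero.
#' @return Cleavage percentage in `[0, 100]`.
#' @examples
#' cleavage_percent(75, 25)  # 75
#' @export
cleavage_percent <- function(cleaved, full_length) {
  if (any(cleaved < 0) || any(full_length < 0)) {
    stop("band intensities must be >= 0")
  }
  total <- cleaved + full_length
  if (any(total == 0)) stop("cleaved and full-length intensities are both zero")
  cleaved * 100 / total
}

#' Read a band-intensity table
#'
#' TSV with header columns `construct`, `n_length`, `strain`, `replicate`,
#' `cleaved`, `full` (as written by [generate_band_table()]).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of band measurements.
#' @export
read_band_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("construct", "n_length", "strain", "replicate", "cleaved", "full")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("band table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Cleavage profile: mean and SD per N-length
#'
#' Averages replicate cleavage percentages per `n_length` for one strain,
#' with the sample standard deviation (n - 1 denominator), sorted by
#' `n_length`. A point with a single replicate reports `sd = 0` with a
#' warning.
#'
#' @param measurements Band-measurement data frame (columns `n_length`,
#'   `strain`, `replicate`, `cleaved`, `full`).
#' @param strain Strain to profile; defaults to the only strain present.
#'   Mixed strains without an explicit choice are an error.
#' @return A `cleavage_profile` tibble with `n_length`, `mean`, `sd`, `n`
#'   and a `strain` attribute.
#' @export
build_profile <- function(measurements, strain = NULL) {
  measurements <- tibble::as_tibble(measurements)
  strains <- unique(measurements$strain)
  if (is.null(strain)) {
    if (length(strains) > 1) {
      stop("measurements mix strains (", paste(strains, collapse = ", "),
           "); pass `strain` explicitly")
    }
    strain <- strains
  }
  dat <- dplyr::filter(measurements, .data$strain == !!strain)
  if (nrow(dat) == 0) stop("no measurements for strain '", strain, "'")
  dat$cleavage <- cleavage_percent(dat$cleaved, dat$full)
  prof <- dat |>
    dplyr::group_by(.data$n_length) |>
    dplyr::summarise(mean = mean(.data$cleavage),
                     sd = if (dplyr::n() > 1) stats::sd(.data$cleavage) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$n_length)
  if (any(prof$n == 1)) {
    warning("single-replicate point(s) at n_length ",
            paste(prof$n_length[prof$n == 1], collapse = ", "),
            "; sd reported as 0")
  }
  structure(prof, strain = strain,
            class = c("cleavage_profile", class(prof)))
}

#' Significance stars for p-values
#'
#' The conventional ladder: `n.s.` for p > 0.05, then `*` (p <= 0.05),
#' `**` (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001), with inclusive
#' thresholds.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Compare two cleavage profiles point by point
#'
#' Per `n_length`, a two-sided two-sample t test between the replicate
#' cleavage percentages of two strains: Welch-Satterthwaite (`"welch"`,
#' unequal variances) or pooled-variance Student (`"student"`). Raw p-values
#' are annotated with significance stars; a Holm-adjusted column is reported
#' alongside for transparency and never replaces the raw values. Points with
#' fewer than 2 replicates in either group are skipped with a warning.
#'
#' @param a,b Band-measurement data frames (replicate level), one strain
#'   each, or a combined frame plus `strains = c(a, b)`.
#' @param test `"welch"` (default) or `"student"`.
#' @param strains Optional pair of strain labels when `a` holds both.
#' @return A `cleavage_comparison` tibble with `n_length`, `mean_a`,
#'   `mean_b`, `t_statistic`, `degrees_of_freedom`, `p_value`, `p_holm`,
#'   `star`.
#' @export
compare_profiles <- function(a, b = NULL, test = c("welch", "student"),
                             strains = NULL) {
  test <- match.arg(test)
  if (is.null(b)) {
    stopifnot(!is.null(strains), length(strains) == 2)
    a <- tibble::as_tibble(a)
    b <- dplyr::filter(a, .data$strain == strains[2])
    a <- dplyr::filter(a, .data$strain == strains[1])
  }
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  a$cleavage <- cleavage_percent(a$cleaved, a$full)
  b$cleavage <- cleavage_percent(b$cleaved, b$full)
  points <- sort(intersect(unique(a$n_length), unique(b$n_length)))
  rows <- list()
  for (nl in points) {
    xa <- a$cleavage[a$n_length == nl]
    xb <- b$cleavage[b$n_length == nl]
    if (length(xa) < 2 || length(xb) < 2) {
      warning("n_length ", nl, " skipped: fewer than 2 replicates in a group")
      next
    }
    tt <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      # degenerate noise-free groups: t.test cannot run; report the limits
      list(statistic = c(t = if (mean(xa) == mean(xb)) 0 else
        sign(mean(xa) - mean(xb)) * Inf),
           parameter = c(df = length(xa) + length(xb) - 2),
           p.value = if (mean(xa) == mean(xb)) 1 else 0)
    } else {
      stats::t.test(xa, xb, var.equal = (test == "student"),
                    alternative = "two.sided")
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      n_length = nl, mean_a = mean(xa), mean_b = mean(xb),
      t_statistic = unname(tt$statistic),
      degrees_of_freedom = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  if (length(rows) == 0) stop("no comparable points")
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$star <- significance_stars(out$p_value)
  structure(out, test = test,
            class = c("cleavage_comparison", class(out)))
}
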