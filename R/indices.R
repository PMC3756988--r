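# Trapezoid rule on the observed grid (no interpolation of missing points).
.trapz <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Empirical glucose-homeostasis index panel
#'
#' Computes, per subject, the standard surrogate indices of insulin
#' sensitivity and beta-cell function from a seven-point OGTT:
#'
#' * `HOMA_IS` = 22.5 / (G_b\[mM\] * I_b\[mU/L\]) — reciprocal HOMA-IR;
#' * `HOMA_BCF` = 20 * I_b\[mU/L\] / (G_b\[mM\] - 3.5);
#' * `IS_NAIF` = 1 / mean of all valid glycemias (1/mM);
#' * `AUCG`, `AUCI` — trapezoid areas under the glucose (mM min) and insulin
#'   (pM min) curves over the observed grid;
#' * `AUCrig` = AUCI / AUCG;
#' * `IGenic` (insulinogenic index) = (I30 - I0) / (G30 - G0), pM/mM;
#' * `G2h` — the 120-min glucose sample (mM).
#'
#' Insulin enters HOMA formulas in mU/L via the configurable conversion
#' factor. Ratios with a zero denominator and indices whose samples are
#' missing are returned as `NA`, never as infinities. Model-inspired indices
#' whose defining algorithms live in external sources (OGIS, ISIcomp, MCRest,
#' IS_BREDA) can be plugged in through `extra`: named functions receiving the
#' subject's observation tibble and returning a scalar.
#'
#' @param data OGTT observations tibble in model units (mM / pM), one or more
#'   subjects.
#' @param insulin_factor pmol/L per mU/L used inside HOMA formulas.
#' @param extra Named list of plug-in index functions.
#' @return A tibble with one row per subject.
#' @export
#' @examples
#' obs <- tibble::tibble(subject = "a", time = seq(0, 180, 30),
#'                       glucose = 5, insulin = 60)
#' ogtt_indices(obs)
ogtt_indices <- function(data, insulin_factor = PM_PER_MUL, extra = list()) {
  data <- .ensure_validity(data)
  if (!"subject" %in% names(data)) data$subject <- "s1"
  one <- function(d) {
    d <- arrange(d, .data$time)
    g <- ifelse(d$glucose_valid, d$glucose, NA_real_)
    i <- ifelse(d$insulin_valid, d$insulin, NA_real_)
    t <- d$time
    at <- function(v, tt) {
      ix <- which(t == tt)
      if (length(ix) && is.finite(v[ix[1]])) v[ix[1]] else NA_real_
    }
    G0 <- at(g, 0); I0 <- at(i, 0)
    G30 <- at(g, 30); I30 <- at(i, 30)
    I0_mU <- I0 / insulin_factor
    ratio_or_na <- function(num, den) {
      if (!is.finite(num) || !is.finite(den) || den == 0) NA_real_
      else num / den
    }
    aucg <- .trapz(t, g)
    auci <- .trapz(t, i)
    out <- tibble(
      subject = d$subject[1],
      group = if ("group" %in% names(d)) d$group[1] else "all",
      HOMA_IS = ratio_or_na(22.5, G0 * I0_mU),
      HOMA_BCF = ratio_or_na(20 * I0_mU, G0 - 3.5),
      IS_NAIF = ratio_or_na(1, mean(g, na.rm = TRUE)),
      AUCG = aucg,
      AUCI = auci,
      AUCrig = ratio_or_na(auci, aucg),
      IGenic = ratio_or_na(I30 - I0, G30 - G0),
      G2h = at(g, 120)
    )
    for (nm in names(extra)) out[[nm]] <- extra[[nm]](d)
    out
  }
  data |>
    dplyr::group_split(.data$subject) |>
    purrr::map(one) |>
    bind_rows()
}
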