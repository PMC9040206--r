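#' Gail-model parameters
#'
#' Logistic coefficients and attributable-risk proportions of a BCRAT-style
#' relative-risk model.  Category codes follow the BCRAT convention: age at
#' menarche >=14/12-13/<12 -> 0/1/2; age at first live birth <20/20-25/25-30
#' (and nulliparous)/>=30 -> 0/1/2/3; ever biopsy no/yes -> 0/1; number of
#' affected first-degree relatives 0/1.  Unknown categories map to the
#' reference (lowest-risk) class.  Two age segments (<50, >=50) carry their
#' own attributable risk and the biopsy coefficient may differ by segment via
#' the biopsy-age interaction.
#'
#' @param coef_menarche,coef_biopsy,coef_first_birth,coef_relatives per-unit
#'   log relative risks for the coded categories.
#' @param coef_biopsy_age50 added to the biopsy term when age >= 50.
#' @param coef_firstbirth_relatives coefficient of the first-birth x
#'   relatives product.
#' @param ar_lt50,ar_ge50 attributable-risk proportions in \[0, 1) for the
#'   two age segments; `1 - AR` rescales composite incidence into the
#'   baseline-category hazard.
#' @param label free-text provenance label.
#' @return List of class `gail_params`.
#' @export
gail_params <- function(coef_menarche, coef_biopsy, coef_first_birth,
                        coef_relatives, coef_biopsy_age50 = 0,
                        coef_firstbirth_relatives = 0,
                        ar_lt50, ar_ge50, label = "custom") {
  for (ar in c(ar_lt50, ar_ge50))
    if (!is.finite(ar) || ar < 0 || ar >= 1)
      stop("gail_params: attributable risks must lie in [0, 1)")
  structure(list(coef_menarche = coef_menarche, coef_biopsy = coef_biopsy,
                 coef_first_birth = coef_first_birth,
                 coef_relatives = coef_relatives,
                 coef_biopsy_age50 = coef_biopsy_age50,
                 coef_firstbirth_relatives = coef_firstbirth_relatives,
                 ar_lt50 = ar_lt50, ar_ge50 = ar_ge50, label = label),
            class = "gail_params")
}

#' Load Gail parameters from a key-value text file
#'
#' One `key = value` pair per line; `#` starts a comment.  Required keys
#' match the arguments of [gail_params()].
#'
#' @param path path to the parameter file; default the bundled
#'   Asian-American (AABCS) parameters.
#' @return A `gail_params` object.
#' @export
load_gail_params <- function(path = system.file("extdata",
                                                "gail_aabcs_params.txt",
                                                package = "riskstrat")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("load_gail_params: malformed line ", bad[1L], " in ", path)
  vals <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  num <- function(k) {
    if (!k %in% names(vals)) stop("load_gail_params: missing key '", k, "'")
    as.numeric(vals[[k]])
  }
  gail_params(coef_menarche = num("coef_menarche"),
              coef_biopsy = num("coef_biopsy"),
              coef_first_birth = num("coef_first_birth"),
              coef_relatives = num("coef_relatives"),
              coef_biopsy_age50 = num("coef_biopsy_age50"),
              coef_firstbirth_relatives = num("coef_firstbirth_relatives"),
              ar_lt50 = num("ar_lt50"), ar_ge50 = num("ar_ge50"),
              label = if ("label" %in% names(vals)) vals[["label"]] else "file")
}

#' Null Gail parameters (population-average projection)
#'
#' All coefficients and attributable risks zero, so every profile has
#' relative risk 1 and [gail_absolute_risk()] reduces to the population-rate
#' projection — the parameterization under which the 5-year risk of an
#' average 50-year-old defines the screening threshold.
#'
#' @return A `gail_params` object.
#' @export
gail_params_null <- function() {
  gail_params(0, 0, 0, 0, 0, 0, ar_lt50 = 0, ar_ge50 = 0,
              label = "population-average (null)")
}

.MENARCHE_CODE <- c(ge14 = 0, "12to13" = 1, lt12 = 2, unknown = 0)
.FIRSTBIRTH_CODE <- c(lt20 = 0, "20to25" = 1, "25to30" = 2, nulliparous = 2,
                      ge30 = 3, unknown = 0)
.BIOPSY_CODE <- c(no = 0, yes = 1, unknown = 0)

.code_of <- function(x, map, what) {
  bad <- setdiff(unique(x), names(map))
  if (length(bad))
    stop("unknown ", what, " category: ", paste(bad, collapse = ", "))
  unname(map[x])
}

#' Gail-model relative risk
#'
#' \eqn{RR = \exp(\sum_k c_k x_k)} over the coded risk-factor categories,
#' with the biopsy-age and first-birth-relatives interaction terms; the
#' age >= 50 segment switches the biopsy-age interaction on.  The
#' all-reference profile has RR exactly 1.  Unknown categories fall to the
#' reference class.
#'
#' @param menarche,first_birth,biopsy character category vectors (see
#'   [gail_params()] for the category sets).
#' @param n_relatives number of affected first-degree relatives (0 or 1).
#' @param age age(s) in years; must be >= 20 (model domain).
#' @param params a `gail_params` object.
#' @return Positive relative risk(s).
#' @examples
#' p <- load_gail_params()
#' gail_relative_risk("ge14", "lt20", "no", 0, 45, p)  # 1
#' @export
gail_relative_risk <- function(menarche, first_birth, biopsy, n_relatives,
                               age, params) {
  stopifnot(inherits(params, "gail_params"))
  if (any(age < 20)) stop("gail_relative_risk: age below model domain (20)")
  if (any(!n_relatives %in% c(0, 1)))
    stop("gail_relative_risk: n_relatives must be 0 or 1")
  am <- .code_of(menarche, .MENARCHE_CODE, "menarche")
  af <- .code_of(first_birth, .FIRSTBIRTH_CODE, "first_birth")
  nb <- .code_of(biopsy, .BIOPSY_CODE, "biopsy")
  lp <- params$coef_menarche * am +
    params$coef_biopsy * nb +
    params$coef_first_birth * af +
    params$coef_relatives * n_relatives +
    params$coef_biopsy_age50 * nb * (age >= 50) +
    params$coef_firstbirth_relatives * af * n_relatives
  exp(lp)
}

#' Gail-model five-year absolute risk
#'
#' Baseline hazard per age interval is composite incidence times
#' `(1 - AR)` of the applicable age segment; the projection multiplies it by
#' the profile's relative risk, re-evaluated per sub-interval so a window
#' crossing age 50 switches both the attributable risk and the biopsy-age
#' interaction mid-window, and integrates against competing mortality as in
#' [five_year_absolute_risk()].
#'
#' @inheritParams gail_relative_risk
#' @param rates a [rates_table()].
#' @param window projection horizon in years (default 5).
#' @return Risk(s) in \[0, 1\], vectorized over the profile arguments.
#' @examples
#' us <- load_rates(system.file("extdata", "us_white_rates.csv",
#'                              package = "riskstrat"))
#' # the ~1.3% average-woman threshold anchor:
#' gail_absolute_risk("ge14", "lt20", "no", 0, 50, us, gail_params_null())
#' @export
gail_absolute_risk <- function(menarche, first_birth, biopsy, n_relatives,
                               age, rates, params, window = 5) {
  stopifnot(inherits(rates, "rates_table"), inherits(params, "gail_params"))
  n <- max(length(menarche), length(first_birth), length(biopsy),
           length(n_relatives), length(age))
  menarche <- rep_len(menarche, n); first_birth <- rep_len(first_birth, n)
  biopsy <- rep_len(biopsy, n); n_relatives <- rep_len(n_relatives, n)
  age <- rep_len(age, n)
  vapply(seq_len(n), function(i) {
    sub <- .split_window(rates, age[i], window, extra_cuts = 50)
    ar <- ifelse(sub$start >= 50, params$ar_ge50, params$ar_lt50)
    rr <- gail_relative_risk(menarche[i], first_birth[i], biopsy[i],
                             n_relatives[i], sub$start, params)
    h <- rr * rates$incidence[sub$idx] * (1 - ar)
    .risk_over_subintervals(h, rates$mortality[sub$idx], sub$end - sub$start)
  }, numeric(1))
}
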