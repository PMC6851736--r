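# EQ-5D tariff scoring. A tariff maps a five-dimension, three-level
# health profile to a utility by additive decrements: a constant
# deduction for any departure from full health, per-dimension decrements
# for levels 2 and 3, and an extra "N3" decrement when any dimension is
# at level 3. Coefficients are configuration, never hardcoded: country
# tariffs differ and the scoring rule is the only fixed part.

.eq5d_dims <- c("mo", "sc", "ua", "pd", "ad")

#' Construct an EQ-5D tariff specification
#'
#' @param full_health Utility of profile 11111 (typically 1).
#' @param constant Deduction applied once for any departure from full
#'   health.
#' @param level2,level3 Named numeric vectors of per-dimension decrements
#'   for level-2 and level-3 responses; names must be `mo`, `sc`, `ua`,
#'   `pd`, `ad` (mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression).
#' @param n3 Extra decrement applied once if any dimension is at level 3.
#' @return An object of class `tariff_spec`.
#' @export
tariff_spec <- function(full_health = 1.0, constant = 0,
                        level2 = c(mo = 0, sc = 0, ua = 0, pd = 0, ad = 0),
                        level3 = c(mo = 0, sc = 0, ua = 0, pd = 0, ad = 0),
                        n3 = 0) {
  level2 <- level2[.eq5d_dims]
  level3 <- level3[.eq5d_dims]
  if (anyNA(level2) || anyNA(level3))
    stop("`level2` and `level3` must name all five dimensions: ",
         paste(.eq5d_dims, collapse = ", "), call. = FALSE)
  decs <- c(constant, level2, level3, n3)
  if (any(decs < 0)) stop("tariff decrements must be >= 0", call. = FALSE)
  structure(list(full_health = full_health, constant = constant,
                 level2 = level2, level3 = level3, n3 = n3),
            class = "tariff_spec")
}

#' Synthetic three-level EQ-5D tariff
#'
#' A round-number tariff with the structure of published three-level
#' value sets (constant term, larger decrements for pain and mobility,
#' an N3 penalty). Intended for simulation and worked examples; real
#' analyses should load a country value set via [read_tariff()].
#'
#' @return A `tariff_spec`.
#' @export
synthetic_tariff <- function() {
  tariff_spec(
    full_health = 1.0, constant = 0.07,
    level2 = c(mo = 0.04, sc = 0.05, ua = 0.03, pd = 0.05, ad = 0.05),
    level3 = c(mo = 0.16, sc = 0.21, ua = 0.10, pd = 0.17, ad = 0.24),
    n3 = 0.23
  )
}

#' Score EQ-5D profiles under a tariff
#'
#' @param profile An integer vector of five levels in `{1, 2, 3}`
#'   (mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression), or a matrix / data frame with one profile per
#'   row.
#' @param tariff A [tariff_spec()].
#' @return Utility value(s): `full_health` for 11111, otherwise
#'   `full_health` minus the constant, the per-dimension decrements and,
#'   if any dimension is at level 3, the N3 decrement.
#' @examples
#' score_eq5d(c(1, 1, 1, 1, 1), synthetic_tariff())  # 1
#' score_eq5d(c(3, 3, 3, 3, 3), synthetic_tariff())
#' @export
score_eq5d <- function(profile, tariff) {
  stopifnot(inherits(tariff, "tariff_spec"))
  m <- if (is.matrix(profile)) profile
       else if (is.data.frame(profile)) as.matrix(profile)
       else matrix(profile, nrow = 1L)
  if (ncol(m) != 5L)
    stop("an EQ-5D profile has exactly 5 dimensions", call. = FALSE)
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 1L) || any(m > 3L))
    stop("EQ-5D levels must be integers in {1, 2, 3}", call. = FALSE)
  at2 <- m == 2L
  at3 <- m == 3L
  dec <- at2 %*% tariff$level2 + at3 %*% tariff$level3
  any_dep <- rowSums(at2 | at3) > 0L
  any3 <- rowSums(at3) > 0L
  u <- tariff$full_health - dec[, 1L] -
    tariff$constant * any_dep - tariff$n3 * any3
  if (is.matrix(profile) || is.data.frame(profile)) u else u[[1L]]
}

#' Read / write a tariff configuration file
#'
#' Tariffs are stored as YAML with keys `full_health`, `constant`,
#' `level2`, `level3` (each a map over `mo`, `sc`, `ua`, `pd`, `ad`) and
#' `n3`.
#'
#' @param path File path.
#' @return `read_tariff()` returns a `tariff_spec`; `write_tariff()`
#'   returns `path` invisibly.
#' @export
read_tariff <- function(path) {
  y <- yaml::read_yaml(path)
  tariff_spec(full_health = y$full_health, constant = y$constant,
              level2 = unlist(y$level2), level3 = unlist(y$level3),
              n3 = y$n3)
}

#' @rdname read_tariff
#' @param tariff A `tariff_spec` to serialize.
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "tariff_spec"))
  yaml::write_yaml(list(full_health = tariff$full_health,
                        constant = tariff$constant,
                        level2 = as.list(tariff$level2),
                        level3 = as.list(tariff$level3),
                        n3 = tariff$n3), path)
  invisible(path)
}
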