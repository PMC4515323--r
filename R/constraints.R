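# ---------------------------------------------------------------------------
# Qualitative calibration constraints for the PKA network, one per published
# strain-panel observation.  Comparisons operate on basin-weighted population
# averages from a predict_panel() run:
#   "greater"/"less"  : strict directional contrast
#   "approx"          : relative difference within the tolerance band
#   "strongly less"   : below `strong` times the comparator
#   "strongly greater": above 1/`strong` times the comparator
# The reported margin is the worst sub-check margin, positive iff the
# constraint passes (approx: tol - relative difference; directional:
# signed relative difference in the required direction minus nothing).
# ---------------------------------------------------------------------------

cmp_rel <- function(a, b) abs(a - b) / max(a, b, .Machine$double.eps)

constraint_checks <- function(sig, tol, strong) {
  gt <- function(a, b) (a - b) / max(a, b, .Machine$double.eps)
  lt <- function(a, b) (b - a) / max(a, b, .Machine$double.eps)
  approx <- function(a, b) tol - cmp_rel(a, b)
  much_less <- function(a, b) strong - a / max(b, .Machine$double.eps)
  much_greater <- function(a, b) a / max(b, .Machine$double.eps) - 1 / strong

  list(
    C1 = function() {
      min(vapply(c("Cdc25", "cAMP", "Tpk1", "Tpk2", "Tpk3"),
                 function(nd) sig("WT", "25C", nd), numeric(1)))
    },
    C2 = function() gt(sig("cdc25", "25C"), sig("WT", "25C")),
    C3 = function() gt(sig("WT", "39C"), sig("WT", "25C")),
    C4 = function() approx(sig("cdc25", "39C"), sig("cdc25", "25C")),
    C5 = function() min(much_less(sig("tpk2", "25C"), sig("WT", "25C")),
                        much_less(sig("tpk2", "39C"), sig("WT", "39C"))),
    C6 = function() min(
      much_less(sig("tpk1 tpk2", "25C"), sig("WT", "25C")),
      much_less(sig("tpk1 tpk2", "39C"), sig("WT", "39C")),
      much_less(sig("tpk2 tpk3", "25C"), sig("WT", "25C")),
      much_less(sig("tpk2 tpk3", "39C"), sig("WT", "39C"))
    ),
    C7 = function() min(approx(sig("tpk1 tpk3", "25C"), sig("WT", "25C")),
                        approx(sig("tpk1 tpk3", "39C"), sig("WT", "39C"))),
    C8 = function() min(approx(sig("tpk2::TPK2 tpk3", "25C"), sig("WT", "25C")),
                        approx(sig("tpk2::TPK2 tpk3", "39C"), sig("WT", "39C"))),
    C9 = function() min(lt(sig("bcy1", "25C"), sig("WT", "25C")),
                        lt(sig("bcy1", "39C"), sig("WT", "39C"))),
    C10 = function() gt(sig("ras2", "25C"), sig("WT", "25C")),
    C11 = function() min(
      gt(sig("ssa2", "25C"), sig("WT", "25C")),
      approx(sig("ssa1", "25C"), sig("WT", "25C")),
      approx(sig("ssa1", "39C"), sig("WT", "39C")),
      much_greater(sig("ssa1 ssa2", "25C"), sig("WT", "25C")),
      much_greater(sig("ssa1 ssa2", "39C"), sig("WT", "39C"))
    ),
    C12 = function() min(
      gt(sig("ssa1 ssa2 tpk2", "25C"), sig("tpk2", "25C")),
      gt(sig("ssa1 ssa2 tpk2", "39C"), sig("tpk2", "39C")),
      approx(sig("ssa1 ssa2 tpk2", "25C"), sig("WT", "25C")),
      lt(sig("ssa1 ssa2 tpk2", "39C"), sig("WT", "39C"))
    ),
    C13 = function() min(
      approx(sig("skn7", "25C"), sig("WT", "25C")),
      approx(sig("skn7", "39C"), sig("WT", "39C")),
      lt(sig("skn7 cdc25", "25C"), sig("cdc25", "25C")),
      lt(sig("skn7 cdc25", "39C"), sig("cdc25", "39C"))
    ),
    C14 = function() min(
      approx(sig("hsf1-dCTA", "25C"), sig("WT", "25C")),
      # no heat induction: 39C level not above the 25C level beyond the band
      (1 + tol) - sig("hsf1-dCTA", "39C") /
        max(sig("hsf1-dCTA", "25C"), .Machine$double.eps),
      lt(sig("hsf1-dCTA cdc25", "25C"), sig("cdc25", "25C")),
      lt(sig("hsf1-dCTA cdc25", "39C"), sig("cdc25", "39C"))
    ),
    C15 = function() min(
      gt(sig("ssa1 ssa2", "39C", "HSE"), sig("WT", "39C", "HSE")),
      gt(sig("ssa1 ssa2", "39C", "Bcy1"), sig("WT", "39C", "Bcy1")),
      lt(sig("ssa1 ssa2", "39C", "cAMP"), sig("WT", "39C", "cAMP")),
      lt(sig("ssa1 ssa2", "39C", "Tpk3"), sig("WT", "39C", "Tpk3"))
    )
  )
}

#' The calibration-constraint suite of the PKA panel
#'
#' Machine-checkable qualitative constraints on basin-weighted HSE-reporter
#' averages (plus pathway nodes for C1 and C15) across the strain panel,
#' each citing the figure of the underlying measurement.
#'
#' @return A tibble with columns `id`, `figure`, `strains` (list-column of
#'   the strains each constraint reads) and `description`.
#' @export
pka_constraints <- function() {
  tibble(
    id = paste0("C", 1:15),
    figure = c("Fig 1", "Fig 2", "Fig 2", "Fig 2", "Fig 5", "Fig 5", "Fig 5",
               "Fig 5", "Fig 4", "Fig 4", "Fig 6", "Fig 6", "Fig 2", "Fig 2",
               "Fig 8"),
    strains = list(
      "WT", c("cdc25", "WT"), "WT", "cdc25",
      c("tpk2", "WT"), c("tpk1 tpk2", "tpk2 tpk3", "WT"),
      c("tpk1 tpk3", "WT"), c("tpk2::TPK2 tpk3", "WT"),
      c("bcy1", "WT"), c("ras2", "WT"),
      c("ssa1", "ssa2", "ssa1 ssa2", "WT"),
      c("ssa1 ssa2 tpk2", "tpk2", "WT"),
      c("skn7", "skn7 cdc25", "cdc25", "WT"),
      c("hsf1-dCTA", "hsf1-dCTA cdc25", "cdc25", "WT"),
      c("ssa1 ssa2", "WT")
    ),
    description = c(
      "wild-type PKA cascade active at 25C (Cdc25, cAMP, Tpk1-3 averages > 0)",
      "HSE expression derepressed in cdc25 relative to WT at 25C",
      "heat shock raises WT HSE expression (39C above 25C)",
      "cdc25 HSE expression unchanged between 25C and 39C",
      "tpk2 strongly repressed at both temperatures",
      "tpk1 tpk2 and tpk2 tpk3 (single remaining CS Tpk3/Tpk1) very low",
      "tpk1 tpk3 (Tpk2 sole CS) similar to WT",
      "restored TPK2 in tpk3 background returns expression to WT levels",
      "bcy1 (constitutive PKA) repressed relative to WT at both temperatures",
      "ras2 constitutively elevated at 25C",
      "ssa2 above WT, ssa1 similar to WT, ssa1 ssa2 far above WT",
      "ssa1 ssa2 tpk2 above tpk2, near WT at 25C, below WT at 39C",
      "skn7 similar to WT; skn7 cdc25 below cdc25",
      "hsf1-dCTA similar to WT at 25C, no heat induction, lowers cdc25 derepression",
      "ssa1 ssa2 at 39C: HSE and Bcy1 high, cAMP and Tpk3 low, versus WT"
    )
  )
}

#' Evaluate the calibration constraints on a predicted panel
#'
#' @param panel A `wdm_panel` from [predict_panel()] covering the strains the
#'   suite references at both temperatures.
#' @param suite Constraint catalogue, defaults to [pka_constraints()].
#' @param tol Relative tolerance band for "similar to" comparisons
#'   (default 0.15).
#' @param strong Ratio threshold under which an average counts as strongly
#'   repressed (default 0.5; its reciprocal bounds "far above").
#' @return A tibble with columns `id`, `figure`, `description`, `margin`
#'   (worst sub-check margin, positive iff satisfied) and `pass`.
#' @export
#' @examples
#' \donttest{
#' panel <- predict_panel(n_samples = 2e4, seed = 1)
#' evaluate_constraints(panel)
#' }
evaluate_constraints <- function(panel, suite = pka_constraints(),
                                 tol = 0.15, strong = 0.5) {
  needed <- unique(c(unlist(suite$strains), "WT"))
  missing <- setdiff(needed, unique(panel$strain))
  if (length(missing) > 0L) {
    abort(sprintf("panel is missing strain(s): %s",
                  paste(missing, collapse = ", ")))
  }
  sig <- function(strain, condition, node = "HSE") {
    v <- panel$sigma[panel$strain == strain & panel$condition == condition &
                       panel$node == node]
    if (length(v) != 1L) {
      abort(sprintf("panel entry (%s, %s, %s) absent or duplicated",
                    strain, condition, node))
    }
    v
  }
  checks <- constraint_checks(sig, tol, strong)
  margin <- vapply(suite$id, function(id) checks[[id]](), numeric(1))
  out <- tibble(id = suite$id, figure = suite$figure,
                description = suite$description,
                margin = unname(margin), pass = unname(margin) > 0)
  class(out) <- c("wdm_constraint_report", class(out))
  out
}
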