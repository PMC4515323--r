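#' Read and write model-definition files
#'
#' Models are stored as JSON with top-level keys `nodes` (name, levels,
#' role) and `rules` (target, regulators, table). Rule tables are written
#' explicitly, flat in mixed-radix order with the first regulator varying
#' fastest (recorded in the file as `table_order`), so a write/read
#' round-trip is lossless.
#'
#' @param path File path.
#' @param network A `discrete_network`.
#' @return `read_model_file()` a validated `discrete_network`;
#'   `write_model_file()` the path, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_model_file(swap_network(), f)
#' identical_network <- read_model_file(f)
read_model_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such model file: %s", path))
  def <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  build_network(def)
}

#' @rdname read_model_file
#' @export
write_model_file <- function(network, path) {
  stopifnot(inherits(network, "discrete_network"))
  def <- list(
    format = "wdmnet-model",
    table_order = "first_regulator_fastest",
    nodes = purrr::pmap(network$nodes, function(name, levels, role) {
      list(name = name, levels = levels, role = role)
    }),
    rules = lapply(network$rules, function(r) {
      list(target = r$target, regulators = as.list(r$regulators),
           table = r$table)
    })
  )
  jsonlite::write_json(def, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a table of experimental expression measurements
#'
#' Expects a CSV with header `strain,condition,mean,sd,n`: reporter
#' activities (for the bundled panel, beta-galactosidase specific activity
#' in nmol ONPG min^-1 mg^-1 protein) per strain and temperature condition,
#' with the standard deviation and replicate count.
#'
#' @param path CSV file path.
#' @param strain_library Optional character vector of known strain names;
#'   unknown strains are flagged with a warning (not an error, so user
#'   panels may extend the bundled library).
#' @return A validated tibble of class `wdm_experimental_table`.
#' @export
read_experimental_table <- function(path,
                                    strain_library = pka_strain_library()$strain) {
  tbl <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  required <- c("strain", "condition", "mean", "sd", "n")
  if (!all(required %in% names(tbl))) {
    abort(sprintf("expected header %s", paste(required, collapse = ",")))
  }
  if (anyNA(tbl$mean) || anyNA(tbl$sd) || anyNA(tbl$n)) {
    abort("malformed rows: missing numeric values")
  }
  if (any(tbl$mean < 0)) abort("negative mean activity")
  if (any(tbl$sd < 0)) abort("negative standard deviation")
  if (any(tbl$n < 1)) abort("replicate count below 1")
  unknown <- setdiff(unique(tbl$strain), strain_library)
  if (length(unknown) > 0L) {
    warning(sprintf("strain(s) not in the bundled library: %s",
                    paste(unknown, collapse = ", ")))
  }
  class(tbl) <- c("wdm_experimental_table", class(tbl))
  tbl
}

#' Compare predicted and observed expression ratios
#'
#' Normalizes the observed means to the reference entry (wild type at
#' optimal temperature), joins them with the predicted ratios on
#' `(strain, condition)`, and summarizes agreement by the rank correlation
#' and the number of sign-concordant deviations from the reference.
#'
#' @param panel A `wdm_panel` from [predict_panel()].
#' @param observed A `wdm_experimental_table`.
#' @param node Reporter node compared (default `"HSE"`).
#' @param reference `c(strain, condition)` reference entry; must be present
#'   in both tables.
#' @return A list of class `wdm_comparison`: `$table` (per-key predicted
#'   ratio, observed ratio, residual) and summary fields; see
#'   [glance.wdm_comparison()].
#' @export
compare_predictions <- function(panel, observed, node = "HSE",
                                reference = c("WT", "25C")) {
  pred <- panel[panel$node == node, c("strain", "condition", "ratio")]
  names(pred)[3L] <- "predicted"
  ref_row <- observed[observed$strain == reference[1L] &
                        observed$condition == reference[2L], ]
  if (nrow(ref_row) != 1L) {
    abort(sprintf("observed table lacks the reference entry (%s, %s)",
                  reference[1L], reference[2L]))
  }
  obs <- tibble(strain = observed$strain, condition = observed$condition,
                observed = observed$mean / ref_row$mean)
  joined <- dplyr::inner_join(pred, obs, by = c("strain", "condition"))
  if (nrow(joined) == 0L) abort("no overlapping (strain, condition) keys")
  joined$residual <- joined$predicted - joined$observed
  rank_cor <- if (nrow(joined) >= 3L) {
    cor(joined$predicted, joined$observed, method = "spearman")
  } else {
    NA_real_
  }
  not_ref <- !(joined$strain == reference[1L] & joined$condition == reference[2L])
  concordant <- sum(sign(joined$predicted[not_ref] - 1) ==
                      sign(joined$observed[not_ref] - 1))
  structure(
    list(table = joined, rank_correlation = rank_cor,
         n_shared = nrow(joined),
         sign_concordant = concordant,
         n_effects = sum(not_ref),
         reference = reference, node = node),
    class = "wdm_comparison"
  )
}

#' @export
print.wdm_comparison <- function(x, ...) {
  cat(sprintf("<prediction/observation comparison: %d shared keys>\n", x$n_shared))
  print(x$table)
  cat(sprintf("rank correlation: %s; sign-concordant effects: %d / %d\n",
              format(x$rank_correlation, digits = 3),
              x$sign_concordant, x$n_effects))
  invisible(x)
}

#' Tidy and summarize a prediction/observation comparison
#'
#' @param x A `wdm_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the per-key table; `glance()`: a one-row tibble with
#'   the rank correlation (NA when fewer than three shared keys make it
#'   undefined), shared-key count and sign-concordance count.
#' @method tidy wdm_comparison
#' @export
tidy.wdm_comparison <- function(x, ...) x$table

#' @rdname tidy.wdm_comparison
#' @method glance wdm_comparison
#' @export
glance.wdm_comparison <- function(x, ...) {
  tibble(rank_correlation = x$rank_correlation, n_shared = x$n_shared,
         sign_concordant = x$sign_concordant, n_effects = x$n_effects)
}

#' Generate a random network fixture
#'
#' Every node receives `in_degree` distinct regulators chosen uniformly at
#' random and a uniformly random total rule table; deterministic given the
#' seed. Used throughout the test suite as the fixture of record for
#' oracle comparisons.
#'
#' @param level_counts Integer vector of per-node level counts (>= 2 each).
#' @param in_degree Number of regulators per node (0 gives a constant
#'   network; at most the node count).
#' @param seed Integer seed.
#' @return A `discrete_network` with nodes `n1`, `n2`, ...
#' @export
#' @examples
#' net <- generate_random_network(c(2, 2, 3), in_degree = 2, seed = 42)
generate_random_network <- function(level_counts, in_degree, seed) {
  level_counts <- as.integer(level_counts)
  n <- length(level_counts)
  if (n < 1L || any(level_counts < 2L)) {
    abort("level_counts must list at least one node with >= 2 levels")
  }
  if (in_degree < 0L || in_degree > n) {
    abort(sprintf("in_degree must lie in 0..%d", n))
  }
  set.seed(seed)
  names <- paste0("n", seq_len(n))
  nodes <- tibble(name = names, levels = level_counts, role = "")
  rules <- lapply(seq_len(n), function(i) {
    regs <- if (in_degree == 0L) character() else sort(sample(names, in_degree))
    reg_levels <- level_counts[match(regs, names)]
    tbl <- sample.int(level_counts[i], size = prod(reg_levels),
                      replace = TRUE) - 1L
    logic_rule(names[i], regs, reg_levels, level_counts[i], tbl)
  })
  discrete_network(nodes, rules)
}
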