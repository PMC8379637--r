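#' Scenario objects
#'
#' A scenario bundles everything needed to plan testing: a table of
#' subpopulations (who is being tested, how prevalent infection is, and what
#' wrong assignments cost), an optional global test budget, and optimizer
#' settings. All population-level functions in the package
#' ([allocate_budget()], [bound_curve()], ...) accept either the
#' subpopulation tibble or a full scenario.
#'
#' Cost units are arbitrary but must be consistent across subpopulations
#' within one scenario: the lower bound and the allocator add
#' `fp_cost`-scaled terms across subpopulations, so "cost 1" has to mean the
#' same thing everywhere.
#'
#' @param name Scenario label.
#' @param subpopulations Data frame with columns `name` (label), `size`
#'   (positive integer count of individuals), `prevalence` (in (0, 1)),
#'   `fp_cost` (cost `b` > 0 of a false positive) and `fn_cost` (cost
#'   `c` > 0 of a false negative).
#' @param budget_tests Optional total number of tests available (>= 0).
#' @param max_k Maximum number of pooling stages to search (default 2).
#' @param max_group Maximum first-stage pool size to search (default 100).
#' @param seed Optional integer seed recorded for simulation runs.
#' @return An object of class `pc_scenario`: a list with the fields above,
#'   `subpopulations` stored as a validated tibble.
#' @examples
#' sc <- scenario("toy",
#'   data.frame(name = "all", size = 1000, prevalence = 0.05,
#'              fp_cost = 1, fn_cost = 20))
#' sc$subpopulations
#' @export
scenario <- function(name, subpopulations, budget_tests = NULL,
                     max_k = 2, max_group = 100, seed = NULL) {
  if (!is.character(name) || length(name) != 1 || is.na(name)) {
    stop("`name` must be a single string.", call. = FALSE)
  }
  sp <- check_subpops(subpopulations)
  if (!is.null(budget_tests)) {
    if (!is.numeric(budget_tests) || length(budget_tests) != 1 ||
        is.na(budget_tests) || budget_tests < 0) {
      stop("`budget_tests` must be a single non-negative number.",
           call. = FALSE)
    }
  }
  if (max_k < 1 || max_k != floor(max_k)) {
    stop("`max_k` must be a positive integer.", call. = FALSE)
  }
  if (max_group < 1 || max_group != floor(max_group)) {
    stop("`max_group` must be a positive integer.", call. = FALSE)
  }
  structure(
    list(
      name = name,
      subpopulations = sp,
      budget_tests = budget_tests,
      max_k = as.integer(max_k),
      max_group = as.integer(max_group),
      seed = seed
    ),
    class = "pc_scenario"
  )
}

#' @export
print.pc_scenario <- function(x, ...) {
  n <- sum(x$subpopulations$size)
  cat(sprintf("<pc_scenario> %s: %d subpopulation(s), N = %s\n",
              x$name, nrow(x$subpopulations), format(n, big.mark = " ")))
  if (!is.null(x$budget_tests)) {
    cat(sprintf("  budget: %s tests (%.4f TpI)\n",
                format(x$budget_tests, big.mark = " "), x$budget_tests / n))
  }
  cat(sprintf("  search: up to %d stage(s), pools up to %d\n",
              x$max_k, x$max_group))
  print(x$subpopulations)
  invisible(x)
}

#' Read or write a scenario configuration file
#'
#' Scenario files are YAML (`.yaml`/`.yml`) or JSON (`.json`) documents with
#' top-level keys `name`, `subpopulations` (a list of records with keys
#' `name`, `size`, `prevalence`, `fp_cost`, `fn_cost`) and optionally
#' `budget_tests`, `max_k`, `max_group`, `seed`. Unknown keys are rejected so
#' typos fail loudly rather than being silently ignored.
#'
#' @param path File path; the extension selects the format.
#' @param x A `pc_scenario` object.
#' @return `read_scenario()` returns a validated [scenario()];
#'   `write_scenario()` returns `path` invisibly. Writing then reading a
#'   scenario reproduces it field for field.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scenario(example35_scenario(), f)
#' read_scenario(f)
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scenario file '%s' does not exist", path), call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("scenario files must end in .yaml, .yml or .json", call. = FALSE)
  }
  allowed <- c("name", "subpopulations", "budget_tests", "max_k",
               "max_group", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown scenario field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$name) || is.null(raw$subpopulations)) {
    stop("scenario files must define `name` and `subpopulations`.",
         call. = FALSE)
  }
  sp_allowed <- c("name", "size", "prevalence", "fp_cost", "fn_cost")
  sp <- purrr::imap_dfr(raw$subpopulations, function(rec, i) {
    unknown <- setdiff(names(rec), sp_allowed)
    if (length(unknown) > 0) {
      stop(sprintf("subpopulation %s: unknown field(s): %s",
                   i, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    missing <- setdiff(sp_allowed, names(rec))
    if (length(missing) > 0) {
      stop(sprintf("subpopulation %s: missing field(s): %s",
                   i, paste(missing, collapse = ", ")), call. = FALSE)
    }
    tibble::tibble(
      name = as.character(rec$name),
      size = as.numeric(rec$size),
      prevalence = as.numeric(rec$prevalence),
      fp_cost = as.numeric(rec$fp_cost),
      fn_cost = as.numeric(rec$fn_cost)
    )
  })
  scenario(
    name = raw$name,
    subpopulations = sp,
    budget_tests = raw$budget_tests,
    max_k = raw$max_k %||% 2,
    max_group = raw$max_group %||% 100,
    seed = raw$seed
  )
}

#' @rdname read_scenario
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "pc_scenario"))
  doc <- list(
    name = x$name,
    subpopulations = purrr::pmap(x$subpopulations, function(...) list(...))
  )
  if (!is.null(x$budget_tests)) doc$budget_tests <- x$budget_tests
  doc$max_k <- x$max_k
  doc$max_group <- x$max_group
  if (!is.null(x$seed)) doc$seed <- x$seed
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("scenario files must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' Packaged scenario: Austria, November 2020
#'
#' Four-subpopulation SARS-CoV-2 surveillance scenario for Austria
#' (population 8 916 845) in mid November 2020, with a budget of 103 621
#' tests (the PCR tests actually used over three days). The population is
#' split by recent-test status (high-prevalence 0.196 vs low-prevalence
#' 0.029) and by health-care employment (false-positive cost 6 vs 1, with a
#' common false-negative cost of 33 chosen so that at prevalence 0.029 a
#' blanket infected assignment costs about the same as a blanket healthy
#' one).
#'
#' @return A [scenario()] with four subpopulations and the historical
#'   test budget.
#' @examples
#' austria_nov2020()
#' @export
austria_nov2020 <- function() {
  read_scenario(system.file("extdata", "austria_nov2020.yaml",
                            package = "poolcost", mustWork = TRUE))
}

#' Single-subpopulation toy scenario
#'
#' One subpopulation with prevalence 1%, false-positive cost 1 and
#' false-negative cost 50: a false negative is fifty times worse than a
#' false positive. With no tests the best default is healthy at expected
#' cost 0.5 per individual; the scarce-test optimum over one- and two-stage
#' strategies is 2SG(66,22).
#'
#' @param size Number of individuals (default one million).
#' @return A [scenario()].
#' @examples
#' no_test_point(example35_scenario()$subpopulations)
#' @export
example35_scenario <- function(size = 1e6) {
  scenario(
    "toy_p01_a50",
    tibble::tibble(name = "all", size = size, prevalence = 0.01,
                   fp_cost = 1, fn_cost = 50)
  )
}

# -- internal -----------------------------------------------------------------

# Accept a pc_scenario or a subpopulation data frame; return the validated
# subpopulation tibble.
as_subpops <- function(x) {
  if (inherits(x, "pc_scenario")) {
    return(x$subpopulations)
  }
  check_subpops(x)
}

check_subpops <- function(subpops) {
  if (!is.data.frame(subpops) || nrow(subpops) == 0) {
    stop("`subpops` must be a data frame with at least one row.",
         call. = FALSE)
  }
  needed <- c("name", "size", "prevalence", "fp_cost", "fn_cost")
  missing <- setdiff(needed, names(subpops))
  if (length(missing) > 0) {
    stop(sprintf("`subpops` is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sp <- tibble::as_tibble(subpops)[needed]
  sp$name <- as.character(sp$name)
  for (col in needed[-1]) {
    if (!is.numeric(sp[[col]]) || anyNA(sp[[col]])) {
      stop(sprintf("column `%s` must be numeric without missing values.",
                   col), call. = FALSE)
    }
  }
  bad_size <- sp$size < 1 | sp$size != floor(sp$size)
  if (any(bad_size)) {
    stop(sprintf("subpopulation '%s': `size` must be a positive integer.",
                 sp$name[which(bad_size)[1]]), call. = FALSE)
  }
  bad_p <- sp$prevalence <= 0 | sp$prevalence >= 1
  if (any(bad_p)) {
    stop(sprintf(
      "subpopulation '%s': `prevalence` must be strictly between 0 and 1.",
      sp$name[which(bad_p)[1]]), call. = FALSE)
  }
  bad_cost <- sp$fp_cost <= 0 | sp$fn_cost <= 0
  if (any(bad_cost)) {
    stop(sprintf(
      "subpopulation '%s': `fp_cost` and `fn_cost` must be positive.",
      sp$name[which(bad_cost)[1]]), call. = FALSE)
  }
  if (anyDuplicated(sp$name)) {
    stop("subpopulation names must be unique.", call. = FALSE)
  }
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
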