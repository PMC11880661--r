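#' Construct a long-format two-trait dataset
#'
#' The package's central data container: one table per trait (one row per
#' measurement) plus one context table (one row per sampling context, e.g. a
#' year) carrying the covariates that drive the correlation reaction norm.
#'
#' @param trait1,trait2 data frames with columns `individual`, `context`,
#'   `value`, plus any covariate columns.
#' @param contexts data frame with column `context` plus context-level
#'   covariate columns; exactly one row per context.
#' @param design one of `"full"`, `"non_repeated"`, `"hybrid"`.  Hybrid
#'   allows repeated trait-1 measurements per (individual, context) but at
#'   most one trait-2 row; non-repeated allows at most one row of each.
#' @param families length-2 character: per-trait response family, each of
#'   `"gaussian"`, `"poisson_log"`, `"poisson_log_trunc"`, `"ordinal_logit"`.
#' @param trait_names optional length-2 character labels.
#' @return An object of class `trait_dataset`.
#' @export
trait_dataset <- function(trait1, trait2, contexts,
                          design = c("hybrid", "non_repeated", "full"),
                          families = c("gaussian", "poisson_log"),
                          trait_names = c("trait1", "trait2")) {
  design <- match.arg(design)
  x <- structure(
    list(trait1 = tibble::as_tibble(trait1),
         trait2 = tibble::as_tibble(trait2),
         contexts = tibble::as_tibble(contexts),
         design = design,
         families = families,
         trait_names = trait_names),
    class = "trait_dataset")
  validate_trait_dataset(x)
  x
}

required_cols <- c("individual", "context", "value")

validate_trait_dataset <- function(x) {
  for (tb in c("trait1", "trait2")) {
    missing <- setdiff(required_cols, names(x[[tb]]))
    if (length(missing)) {
      stop(sprintf("missing column(s) in %s: %s", tb,
                   paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(x[[tb]][required_cols])) {
      stop(sprintf("missing values in required columns of %s", tb),
           call. = FALSE)
    }
  }
  if (!"context" %in% names(x$contexts)) {
    stop("missing column(s) in contexts: context", call. = FALSE)
  }
  if (anyDuplicated(x$contexts$context)) {
    stop("contexts table must have one row per context", call. = FALSE)
  }
  seen <- unique(c(as.character(x$trait1$context),
                   as.character(x$trait2$context)))
  orphans <- setdiff(seen, as.character(x$contexts$context))
  if (length(orphans)) {
    stop(sprintf("context(s) present in trait tables but absent from the context table: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  dup <- function(tb) {
    key <- paste(x[[tb]]$individual, x[[tb]]$context, sep = "\r")
    unique(key[duplicated(key)])
  }
  if (x$design %in% c("non_repeated")) {
    for (tb in c("trait1", "trait2")) {
      d <- dup(tb)
      if (length(d)) {
        stop(sprintf("duplicate (individual, context) measurements in %s under a non-repeated design: %d offending pair(s), e.g. %s",
                     tb, length(d), gsub("\r", "/", d[1])), call. = FALSE)
      }
    }
  }
  if (x$design == "hybrid") {
    d <- dup("trait2")
    if (length(d)) {
      stop(sprintf("duplicate (individual, context) measurements in trait2 under a hybrid design: %d offending pair(s), e.g. %s",
                   length(d), gsub("\r", "/", d[1])), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> design=%s, traits: %s [%s] / %s [%s]\n",
              x$design, x$trait_names[1], x$families[1],
              x$trait_names[2], x$families[2]))
  cat(sprintf("  trait1: %d rows, trait2: %d rows, contexts: %d\n",
              nrow(x$trait1), nrow(x$trait2), nrow(x$contexts)))
  invisible(x)
}

#' Check a dataset against a model variant's sampling-design assumptions
#'
#' Reports, per structural invariant, whether the data satisfy the chosen
#' variant.  Under a non-repeated design it also warns that the estimated
#' observation-level correlation blends among- and within-individual
#' correlations weighted by repeatability, and is at risk of sign bias when
#' repeatabilities are low and the two correlations have opposite signs.
#'
#' @param dataset a [trait_dataset()].
#' @param variant `"full"`, `"non_repeated"` or `"hybrid"` (or a
#'   [crn_model_spec()] whose variant is used).
#' @return data frame with columns `check`, `pass`, `detail`.
#' @export
validate_design <- function(dataset, variant) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (inherits(variant, "crn_model_spec")) variant <- variant$variant
  variant <- match.arg(variant, c("full", "non_repeated", "hybrid"))
  n_rep <- function(tb) {
    key <- paste(dataset[[tb]]$individual, dataset[[tb]]$context)
    sum(duplicated(key))
  }
  rep1 <- n_rep("trait1"); rep2 <- n_rep("trait2")
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail)
  }
  if (variant == "non_repeated") {
    add("trait1 single measurement per (individual, context)", rep1 == 0,
        sprintf("%d repeated rows", rep1))
    add("trait2 single measurement per (individual, context)", rep2 == 0,
        sprintf("%d repeated rows", rep2))
  } else if (variant == "hybrid") {
    add("trait1 has repeated measurements", rep1 > 0,
        sprintf("%d repeated rows", rep1))
    add("trait2 single measurement per (individual, context)", rep2 == 0,
        sprintf("%d repeated rows", rep2))
  } else {
    add("trait1 has repeated measurements", rep1 > 0,
        sprintf("%d repeated rows", rep1))
    add("trait2 has repeated measurements", rep2 > 0,
        sprintf("%d repeated rows", rep2))
    add("traits pairwise aligned", nrow(dataset$trait1) == nrow(dataset$trait2),
        sprintf("%d vs %d rows", nrow(dataset$trait1), nrow(dataset$trait2)))
  }
  out <- do.call(rbind, checks)
  if (variant == "non_repeated") {
    message("non-repeated design: the estimated correlation is at the ",
            "observation level; it equals the among-individual correlation ",
            "only for highly repeatable traits and can even flip sign when ",
            "repeatabilities are low and the within-individual correlation ",
            "has opposite sign (see observation_level_correlation()).")
  }
  out
}

#' Write a trait dataset to a directory of CSV files
#'
#' Emits `trait1.csv`, `trait2.csv`, `contexts.csv` (UTF-8, comma-separated,
#' header row, `.` decimal) plus `metadata.yaml` recording design, families
#' and trait names, so the dataset round-trips through
#' [read_trait_tables()].
#'
#' @param x a [trait_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trait_dataset <- function(x, dir) {
  stopifnot(inherits(x, "trait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$trait1, file.path(dir, "trait1.csv"))
  readr::write_csv(x$trait2, file.path(dir, "trait2.csv"))
  readr::write_csv(x$contexts, file.path(dir, "contexts.csv"))
  yaml::write_yaml(list(design = x$design,
                        families = as.list(x$families),
                        trait_names = as.list(x$trait_names)),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read and validate a directory of trait tables
#'
#' Expects `trait1.csv`, `trait2.csv`, `contexts.csv` and (optionally)
#' `metadata.yaml` as written by [write_trait_dataset()].  All structural
#' invariants are enforced on load; context IDs are treated as opaque
#' strings.
#'
#' @param dir directory containing the CSV files.
#' @param design,families,trait_names overrides for the metadata file (all
#'   required if `metadata.yaml` is absent).
#' @param quiet suppress the row-count report.
#' @return A validated [trait_dataset()].
#' @export
read_trait_tables <- function(dir, design = NULL, families = NULL,
                              trait_names = NULL, quiet = FALSE) {
  files <- file.path(dir, c("trait1.csv", "trait2.csv", "contexts.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta_path <- file.path(dir, "metadata.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  design <- design %||% meta$design
  families <- families %||% unlist(meta$families)
  trait_names <- trait_names %||%
    (if (!is.null(meta$trait_names)) unlist(meta$trait_names) else c("trait1", "trait2"))
  if (is.null(design) || is.null(families)) {
    stop("metadata.yaml absent: supply `design` and `families`", call. = FALSE)
  }
  rd <- function(f) {
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      individual = readr::col_character(),
                      context = readr::col_character(),
                      .default = readr::col_guess()))
  }
  ctx <- readr::read_csv(files[3], show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           context = readr::col_character(),
                           .default = readr::col_guess()))
  x <- trait_dataset(rd(files[1]), rd(files[2]), ctx,
                     design = design, families = families,
                     trait_names = trait_names)
  if (!quiet) {
    per_ctx <- table(as.character(x$trait1$context))
    message(sprintf(
      "read %d trait-1 rows, %d trait-2 rows, %d contexts (trait-1 rows/context: min %d, max %d)",
      nrow(x$trait1), nrow(x$trait2), nrow(x$contexts),
      min(per_ctx), max(per_ctx)))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
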