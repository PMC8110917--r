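#' Grouped k-fold partition plan
#'
#' Assigns biological samples (not individual images) to `train`,
#' `validation` and `holdout` partitions for each fold of a
#' cross-validation. Partitioning at the sample level prevents leakage
#' between near-identical images of one construct: all images of a sample
#' always share one partition within a fold.
#'
#' Two holdout schemes are offered. The default, `"fixed"`, draws one
#' global holdout set that is entirely segregated from training in every
#' fold — the stricter reading of a holdout. `"rotating"` cycles
#' equal-size holdout blocks across folds as in a conventional k-fold
#' split.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param fold_count number of folds (>= 2).
#' @param holdout_fraction,validation_fraction fractions in (0, 1) with
#'   sum < 1; the remainder of each fold is the training partition.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @param scheme `"fixed"` or `"rotating"` holdout (see above).
#' @return A `partition_plan`: list with `fold_count`, `seed`, `scheme`
#'   and `assignments`, a data frame with columns `sample_id`, `fold`,
#'   `partition` containing every sample exactly once per fold.
#' @export
make_partitions <- function(sample_ids, fold_count = 5,
                            holdout_fraction = 0.2,
                            validation_fraction = 0.2, seed = 1,
                            scheme = c("fixed", "rotating")) {
  scheme <- match.arg(scheme)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop_validation("sample_ids must be unique")
  assert_scalar_number(fold_count, "fold_count", lower = 2)
  assert_scalar_number(holdout_fraction, "holdout_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(validation_fraction, "validation_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (holdout_fraction + validation_fraction >= 1)
    stop_validation("holdout_fraction + validation_fraction must be < 1")
  n <- length(sample_ids)
  n_hold <- round(n * holdout_fraction)
  n_val <- round(n * validation_fraction)
  n_train <- n - n_hold - n_val
  if (n_hold < 1L || n_val < 1L || n_train < 1L || n < fold_count) {
    n_min <- ceiling(max(fold_count, 1 / holdout_fraction,
                         1 / validation_fraction,
                         1 / (1 - holdout_fraction - validation_fraction)))
    stop_validation("too few samples (", n, ") for non-empty partitions ",
                    "across ", fold_count, " folds; need at least ", n_min)
  }
  assignments <- with_seed(seed, {
    if (scheme == "fixed") {
      holdout <- sample(sample_ids, n_hold)
      rest <- setdiff(sample_ids, holdout)
      do.call(rbind, lapply(seq_len(fold_count), function(f) {
        val <- sample(rest, n_val)
        data.frame(
          sample_id = c(holdout, val, setdiff(rest, val)),
          fold = f,
          partition = rep(c("holdout", "validation", "train"),
                          c(n_hold, n_val, length(rest) - n_val)),
          stringsAsFactors = FALSE
        )
      }))
    } else {
      shuffled <- sample(sample_ids)
      blocks <- split(shuffled,
                      rep_len(seq_len(fold_count), length(shuffled)))
      do.call(rbind, lapply(seq_len(fold_count), function(f) {
        holdout <- blocks[[f]]
        rest <- setdiff(sample_ids, holdout)
        val <- sample(rest, min(n_val, length(rest) - 1L))
        data.frame(
          sample_id = c(holdout, val, setdiff(rest, val)),
          fold = f,
          partition = rep(c("holdout", "validation", "train"),
                          c(length(holdout), length(val),
                            length(rest) - length(val))),
          stringsAsFactors = FALSE
        )
      }))
    }
  })
  rownames(assignments) <- NULL
  structure(
    list(fold_count = as.integer(fold_count), seed = seed, scheme = scheme,
         assignments = assignments),
    class = "partition_plan"
  )
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> %d folds, %d samples, %s holdout, seed %s\n",
              x$fold_count, length(unique(x$assignments$sample_id)),
              x$scheme, format(x$seed)))
  print(table(x$assignments$fold, x$assignments$partition))
  invisible(x)
}

plan_lookup <- function(plan, fold, partition) {
  a <- plan$assignments
  a$sample_id[a$fold == fold & a$partition == partition]
}

#' Verify a partition plan has no leakage
#'
#' Checks that within every fold the three partitions are disjoint and
#' cover all samples exactly once, and (for the fixed scheme) that the
#' holdout set is identical in every fold, i.e. entirely segregated from
#' training throughout.
#'
#' @param plan a `partition_plan`.
#' @return `TRUE` invisibly; stops with a validation error on any leak.
#' @export
check_partition_plan <- function(plan) {
  stopifnot(inherits(plan, "partition_plan"))
  a <- plan$assignments
  ids <- unique(a$sample_id)
  for (f in seq_len(plan$fold_count)) {
    af <- a[a$fold == f, ]
    if (anyDuplicated(af$sample_id))
      stop_validation("fold ", f, ": sample assigned to multiple partitions")
    if (!setequal(af$sample_id, ids))
      stop_validation("fold ", f, ": partitions do not cover all samples")
  }
  if (plan$scheme == "fixed") {
    h1 <- sort(plan_lookup(plan, 1, "holdout"))
    for (f in seq_len(plan$fold_count))
      if (!identical(sort(plan_lookup(plan, f, "holdout")), h1))
        stop_validation("fixed holdout differs between folds 1 and ", f)
  }
  invisible(TRUE)
}

#' Mean percent error of one fold partition
#'
#' Averages per-sample percent errors (measured vs reference density) over
#' the samples of one partition of one fold — the per-partition error
#' entries of a cross-validation table.
#'
#' @param results data frame with columns `sample_id`,
#'   `reference_density`, `measured_density`.
#' @param plan a `partition_plan`.
#' @param fold fold number.
#' @param partition `"train"`, `"validation"` or `"holdout"`.
#' @return A `fold_error_report`: list with `fold`, `partition`,
#'   `percent_error`.
#' @export
partition_error <- function(results, plan, fold,
                            partition = c("train", "validation", "holdout")) {
  partition <- match.arg(partition)
  stopifnot(inherits(plan, "partition_plan"))
  results <- as.data.frame(results)
  need <- c("sample_id", "reference_density", "measured_density")
  if (!all(need %in% names(results)))
    stop_validation("results must have columns: ", paste(need, collapse = ", "))
  members <- plan_lookup(plan, fold, partition)
  outside <- setdiff(results$sample_id, members)
  if (length(outside))
    stop_validation("sample '", outside[1], "' is not in fold ", fold,
                    " partition '", partition, "'")
  if (nrow(results) == 0L)
    stop_validation("no results supplied for fold ", fold, " '", partition, "'")
  pe <- mapply(percent_error, results$reference_density,
               results$measured_density)
  structure(
    list(fold = as.integer(fold), partition = partition,
         percent_error = mean(pe)),
    class = "fold_error_report"
  )
}

#' Compare test-only and combined test+train accuracies
#'
#' Absolute difference of the mean accuracies of two report sets — used to
#' check that including training images in a dataset does not skew the
#' reported accuracy (a small difference, a couple of percentage points,
#' justifies pooling).
#'
#' @param test_only_accuracies,combined_accuracies non-empty numeric
#'   vectors of percent accuracies.
#' @return Absolute difference of the means, in percentage points.
#' @export
compare_test_vs_combined <- function(test_only_accuracies,
                                     combined_accuracies) {
  if (length(test_only_accuracies) == 0L || length(combined_accuracies) == 0L)
    stop_validation("both accuracy lists must be non-empty")
  abs(mean(test_only_accuracies) - mean(combined_accuracies))
}

#' Write / read a partition plan as CSV
#'
#' Columns `sample_id, fold, partition`; the plan metadata (`fold_count`,
#' `seed`, `scheme`) is rederivable from the assignments except the seed,
#' which is stored as a comment-free extra column on write and ignored on
#' read.
#'
#' @param plan a `partition_plan`.
#' @param path CSV path.
#' @return `path` invisibly (write); a data frame of assignments (read).
#' @export
write_partitions <- function(plan, path) {
  stopifnot(inherits(plan, "partition_plan"))
  utils::write.csv(plan$assignments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  if (!file.exists(path))
    stop_io("cannot read partitions: no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
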