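# 5-fold cross-validation planning: every image lands in exactly one
# validation fold; folds are balanced to within one image and stratified by
# presence of the diseased class so each fold sees both classes.

# run expr under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Plan a k-fold cross-validation split
#'
#' Deterministic under a fixed seed.  Images are shuffled within strata
#' (contains a diseased instance / does not) and assigned folds cyclically,
#' which keeps overall fold sizes within one of each other and spreads the
#' rarer stratum across all folds.
#'
#' @param image_ids character vector of unique image identifiers.
#' @param k number of folds (5 in the evaluation protocol).
#' @param seed integer seed.
#' @param diseased optional logical vector along `image_ids`: stratification
#'   key (image contains a diseased instance).
#' @return object of class `fold_plan`: list with `k`, `seed` and
#'   `assignment` (named integer vector, image id -> fold in 1..k).
#' @export
make_folds <- function(image_ids, k = 5L, seed = 0L, diseased = NULL) {
  n <- length(image_ids)
  if (anyDuplicated(image_ids)) stop("image ids must be unique")
  if (k > n) stop("k (", k, ") exceeds the number of images (", n, ")")
  if (is.null(diseased)) diseased <- rep(FALSE, n)
  stopifnot(length(diseased) == n)
  ord <- with_local_seed(seed, {
    pos <- sample.int(n)   # random order, then stable partition by stratum
    pos[order(!diseased[pos])]
  })
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% k + 1L
  plan <- list(k = as.integer(k), seed = as.integer(seed),
               assignment = setNames(fold, image_ids))
  class(plan) <- "fold_plan"
  plan
}

#' Instance bookkeeping per fold
#'
#' Mirrors the usual cross-validation data-distribution table: for every fold
#' and class, the number of training and validation instances.  Within each
#' fold, training + validation counts sum to the dataset totals.
#'
#' @param plan a [make_folds()] plan.
#' @param boxes_by_image named list (by image id) of box data.frames with a
#'   `class_id` column.
#' @param class_names optional names for the class columns.
#' @return data.frame with columns `fold`, `split`, one column per class,
#'   and `total`.
#' @export
fold_instance_table <- function(plan, boxes_by_image, class_names = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- names(plan$assignment)
  classes <- sort(unique(unlist(lapply(boxes_by_image, function(b) b$class_id))))
  if (is.null(class_names)) class_names <- paste0("class", classes)
  counts <- t(vapply(ids, function(id) {
    b <- boxes_by_image[[id]]
    vapply(classes, function(cl) sum(b$class_id == cl), numeric(1))
  }, numeric(length(classes))))
  rows <- list()
  for (f in seq_len(plan$k)) {
    val <- plan$assignment[ids] == f
    for (split in c("train", "val")) {
      sel <- if (split == "train") !val else val
      cnt <- colSums(counts[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, split = split, t(cnt), total = sum(cnt))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2L + seq_along(classes)] <- class_names
  out
}
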