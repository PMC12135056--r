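#' Assemble the clustering feature table
#'
#' One row per subject: the two PPK covariates plus the plasma concentration
#' at the two anchor times (default 10 and 40 min - the end of the reference
#' infusion and a point in the elimination phase).
#'
#' @param population a `pk_population`.
#' @param profiles list of `conc_profile` objects containing the anchor times
#'   exactly (names or order matching `population$id`).
#' @param anchor_times the two anchor times in min.
#' @return data frame with columns `id`, `age`, `lbm`, `cp<anchor1>`,
#'   `cp<anchor2>`; no missing values.
#' @export
build_cluster_features <- function(population, profiles,
                                   anchor_times = c(10, 40)) {
  if (nrow(population) == 0) {
    out <- data.frame(id = integer(), age = numeric(), lbm = numeric())
    out[paste0("cp", anchor_times)] <- list(numeric(), numeric())
    return(out)
  }
  prof_for <- profile_lookup(profiles, population$id)
  anchors <- t(vapply(population$id, function(sid) {
    p <- prof_for(sid)
    vapply(anchor_times, function(tt) profile_cp_at(p, tt), numeric(1))
  }, numeric(length(anchor_times))))
  colnames(anchors) <- paste0("cp", anchor_times)
  out <- data.frame(id = population$id, age = population$age,
                    lbm = population$lbm)
  out <- cbind(out, anchors)
  if (anyNA(out)) stop_pkmlval("missing values in cluster features")
  out
}

profile_lookup <- function(profiles, ids) {
  if (!is.null(names(profiles))) {
    function(sid) {
      p <- profiles[[as.character(sid)]]
      if (is.null(p)) stop_pkmlval("no profile for subject ", sid)
      p
    }
  } else {
    idx <- match(ids, vapply(profiles, `[[`, numeric(1), "subject_id"))
    if (anyNA(idx)) stop_pkmlval("profiles missing for some subjects")
    function(sid) profiles[[idx[match(sid, ids)]]]
  }
}

#' Agglomerative clustering of the virtual population
#'
#' Ward-linkage hierarchical clustering (`stats::hclust`, `ward.D2`) on the
#' Euclidean distances between subject feature vectors. By default features
#' enter in their raw units (years, kg, ug/L), matching the common default of
#' agglomerative-clustering implementations; set `scale = TRUE` to z-score
#' them first.
#'
#' @param features output of [build_cluster_features()].
#' @param k number of clusters (<= number of subjects).
#' @param scale z-score the feature columns before clustering?
#' @return an object of class `cluster_assignment`: list with `labels` (named
#'   integer vector, one label in `1..k` per subject), `k`, `features`,
#'   `centroids` (k x p, in the clustering space) and `dist` (symmetric k x k
#'   centroid distance matrix, zero diagonal).
#' @export
cluster_population <- function(features, k = 10, scale = FALSE) {
  x <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  n <- nrow(x)
  if (k < 1 || k > n) stop_pkmlval("k must be between 1 and the number of subjects")
  if (scale) x <- base::scale(x)
  labels <- if (k == 1) rep(1L, n) else {
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = k)
  }
  names(labels) <- as.character(features$id)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  rownames(centroids) <- seq_len(k)
  d <- as.matrix(stats::dist(centroids))
  dimnames(d) <- list(seq_len(k), seq_len(k))
  structure(list(labels = labels, k = k, features = features,
                 centroids = centroids, dist = d, scaled = scale),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d subjects in %d clusters (%s features)\n",
              length(x$labels), x$k, if (x$scaled) "z-scored" else "raw"))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Select test cluster and near/far training clusters
#'
#' Picks the test cluster (uniformly at random unless given), identifies the
#' training clusters whose centroids are nearest and farthest from it
#' (Euclidean distance in the clustering space, ties broken toward the lowest
#' label), samples `test_size` test subjects uniformly from the test cluster,
#' and draws nested training subsets of the requested sizes (without
#' replacement) from each of the two training clusters. A subset larger than
#' its source cluster is capped at the cluster size.
#'
#' @param assignment a [cluster_population()] result.
#' @param test_label test cluster label, or `NULL` to choose at random.
#' @param test_size number of test subjects.
#' @param sizes requested training-subset sizes.
#' @param seed integer seed; fixed seed gives an identical split.
#' @return an object of class `split_spec`: test/near/far labels, centroid
#'   distances, `test_ids`, and `train`, a list `near`/`far` each holding a
#'   named list of id vectors per size (nested: smaller subsets are prefixes
#'   of larger ones).
#' @export
select_splits <- function(assignment, test_label = NULL, test_size = 100,
                          sizes = c(1000, 500, 100, 50, 10), seed = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  k <- assignment$k
  if (k < 2) stop_pkmlval("need at least 2 clusters to form train/test splits")
  with_seed_or_not(seed, {
    if (is.null(test_label)) test_label <- sample.int(k, 1)
    if (!test_label %in% seq_len(k)) stop_pkmlval("invalid test cluster label")
    d <- assignment$dist[test_label, ]
    d[test_label] <- NA
    far_label <- unname(which.max(d))  # first (lowest) label wins on ties
    near_label <- unname(which.min(d))
    ids <- names(assignment$labels)
    test_pool <- ids[assignment$labels == test_label]
    if (length(test_pool) < test_size) {
      stop_pkmlval("test cluster has ", length(test_pool),
                   " members; cannot draw ", test_size, " test subjects")
    }
    test_ids <- sample(test_pool, test_size)
    draw_nested <- function(label) {
      pool <- setdiff(ids[assignment$labels == label], test_ids)
      if (length(pool) == 0) stop_pkmlval("training cluster ", label, " is empty")
      ordered <- sample(pool, min(max(sizes), length(pool)))
      out <- lapply(sizes, function(s) ordered[seq_len(min(s, length(ordered)))])
      names(out) <- as.character(sizes)
      out
    }
    structure(list(test_label = test_label, near_label = near_label,
                   far_label = far_label,
                   near_distance = unname(d[near_label]),
                   far_distance = unname(d[far_label]),
                   test_ids = test_ids,
                   train = list(near = draw_nested(near_label),
                                far = draw_nested(far_label)),
                   sizes = sizes, seed = seed),
              class = "split_spec")
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Split: test cluster %d (n=%d), near %d (d=%.2f), far %d (d=%.2f)\n",
              x$test_label, length(x$test_ids), x$near_label, x$near_distance,
              x$far_label, x$far_distance))
  for (cl in names(x$train)) {
    cat(sprintf("  %s subsets: %s\n", cl,
                paste(vapply(x$train[[cl]], length, 1L), collapse = ", ")))
  }
  invisible(x)
}

#' Serialise a split specification
#'
#' JSON round-trip of labels, seed and id lists so an experiment is exactly
#' re-runnable.
#'
#' @param spec a `split_spec`.
#' @param path file path.
#' @return `read_split_spec` returns a `split_spec`.
#' @export
write_split_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_spec
#' @export
read_split_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$train <- lapply(obj$train, function(cl) {
    if (is.data.frame(cl)) cl <- as.list(cl)
    lapply(cl, as.character)
  })
  obj$test_ids <- as.character(obj$test_ids)
  structure(obj, class = "split_spec")
}
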