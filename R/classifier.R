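#' Feature sets of the nearest-centroid classifier variants
#'
#' The original subtype classifier works on age at diabetes onset, BMI,
#' HOMA2-B, HOMA2-IR and HbA1c. When HbA1c is unavailable across all exams,
#' a modified variant substitutes fasting plasma glucose for HbA1c, and a
#' glycemia-free variant omits the glycemic feature entirely.
#'
#' @param variant One of `"hba1c"`, `"fpg"`, `"glycemia_free"`.
#' @return Character vector of feature names, in canonical order.
#' @export
variant_features <- function(variant = c("fpg", "hba1c", "glycemia_free")) {
  variant <- match.arg(variant)
  switch(variant,
    hba1c = c("age_at_onset", "bmi", "hba1c", "homa_b", "homa_ir"),
    fpg = c("age_at_onset", "bmi", "fpg", "homa_b", "homa_ir"),
    glycemia_free = c("age_at_onset", "bmi", "homa_b", "homa_ir")
  )
}

#' Z-score features against frozen standardization parameters
#'
#' @param features A data frame (or single named vector) of raw feature
#'   values.
#' @param standardization A tibble with columns `feature`, `mean`, `sd`
#'   (all `sd` > 0), typically frozen from a training cohort.
#' @return A numeric matrix of standardized values, columns in the order of
#'   `standardization$feature`.
#' @export
standardize <- function(features, standardization) {
  if (is.numeric(features) && !is.null(names(features))) {
    features <- tibble::as_tibble(as.list(features))
  }
  missing <- setdiff(standardization$feature, names(features))
  if (length(missing) > 0) {
    stop_contract(sprintf(
      "features are missing: %s", paste(missing, collapse = ", ")
    ))
  }
  if (any(standardization$sd <= 0)) {
    stop_contract("all standardization SDs must be > 0")
  }
  x <- as.matrix(features[, standardization$feature, drop = FALSE])
  sweep(sweep(x, 2, standardization$mean, "-"), 2, standardization$sd, "/")
}

destandardize <- function(z, standardization) {
  z <- matrix(z,
    ncol = nrow(standardization),
    dimnames = list(NULL, standardization$feature)
  )
  sweep(sweep(z, 2, standardization$sd, "*"), 2, standardization$mean, "+")
}

new_subtype_centroids <- function(variant, feature_names, standardization,
                                  centroids, provenance) {
  stopifnot(
    identical(sort(rownames(centroids)), sort(subtype_levels())),
    ncol(centroids) == length(feature_names)
  )
  structure(
    list(
      variant = variant, feature_names = feature_names,
      standardization = standardization,
      centroids = centroids[subtype_levels(), , drop = FALSE],
      provenance = provenance
    ),
    class = "subtype_centroids"
  )
}

#' @export
print.subtype_centroids <- function(x, ...) {
  cat(sprintf(
    "<subtype_centroids> variant '%s' (%s), features: %s\n",
    x$variant, x$provenance, paste(x$feature_names, collapse = ", ")
  ))
  print(round(x$centroids, 3))
  invisible(x)
}

#' Fit subtype centroids by k-means on a training cohort
#'
#' Freezes per-feature means/SDs from the (GADA-negative) training rows,
#' z-scores them, runs k-means with `k = 4` (Euclidean, best of
#' `k_means_restarts` seeded starts), and labels the four cluster centers by
#' the defining characteristics of the subtypes: the center with the lowest
#' HOMA2-B is SIDD (beta-cell failure), the highest HOMA2-IR among the rest
#' is SIRD (insulin resistance), the highest BMI among the remaining two is
#' MOD (obesity), and the last is MARD.
#'
#' @param training Data frame holding the variant's feature columns
#'   (see [variant_features()]); GADA-negative individuals only.
#' @param variant Classifier variant.
#' @param k_means_restarts Number of random k-means starts.
#' @param seed RNG seed for the k-means starts.
#' @return A `subtype_centroids` object.
#' @export
fit_centroids <- function(training, variant = "fpg", k_means_restarts = 25,
                          seed = 1L) {
  feats <- variant_features(variant)
  require_columns(training, feats, "training")
  x <- training[, feats, drop = FALSE]
  if (nrow(x) < 4 || anyNA(x)) {
    stop_diabtraj("need >= 4 complete training rows", "fitting_error")
  }
  mu <- vapply(x, mean, numeric(1))
  sdev <- vapply(x, sd, numeric(1))
  if (any(sdev == 0)) {
    stop_diabtraj(
      sprintf(
        "zero-variance feature(s): %s",
        paste(feats[sdev == 0], collapse = ", ")
      ),
      "fitting_error"
    )
  }
  standardization <- tibble::tibble(
    feature = feats, mean = unname(mu), sd = unname(sdev)
  )
  z <- standardize(x, standardization)
  km <- with_preserved_seed(
    seed,
    kmeans(z, centers = 4, nstart = k_means_restarts, iter.max = 100)
  )
  centers <- km$centers
  labels <- label_centroid_clusters(centers, standardization)
  rownames(centers) <- labels
  new_subtype_centroids(
    variant, feats, standardization, centers,
    provenance = "fitted_by_kmeans"
  )
}

# label 4 cluster centers (rows, standardized space) as SIDD/SIRD/MOD/MARD
label_centroid_clusters <- function(centers, standardization) {
  stopifnot(nrow(centers) == 4)
  labels <- rep(NA_character_, 4)
  remaining <- seq_len(4)
  pick <- function(col, which_fun) {
    i <- remaining[which_fun(centers[remaining, col])]
    remaining <<- setdiff(remaining, i)
    i
  }
  labels[pick("homa_b", which.min)] <- "SIDD"
  labels[pick("homa_ir", which.max)] <- "SIRD"
  labels[pick("bmi", which.max)] <- "MOD"
  labels[remaining] <- "MARD"
  labels
}

#' Save / load subtype centroids
#'
#' Centroid files are YAML with the variant tag, feature names, frozen
#' standardization means/SDs and the four centroid rows (standardized
#' space). This lets externally published centroids be supplied instead of
#' refitting.
#'
#' @param centroids A `subtype_centroids` object.
#' @param path YAML file path.
#' @return `load_centroids()` returns a `subtype_centroids` object.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "subtype_centroids"))
  obj <- list(
    variant = centroids$variant,
    feature_names = as.list(centroids$feature_names),
    mean = as.list(setNames(
      centroids$standardization$mean,
      centroids$standardization$feature
    )),
    sd = as.list(setNames(
      centroids$standardization$sd,
      centroids$standardization$feature
    )),
    centroids = lapply(
      setNames(nm = rownames(centroids$centroids)),
      function(s) as.list(setNames(
        centroids$centroids[s, ],
        colnames(centroids$centroids)
      ))
    )
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_centroids
#' @export
load_centroids <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("centroid file not found: %s", path))
  obj <- yaml::read_yaml(path)
  need <- c("variant", "feature_names", "mean", "sd", "centroids")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0) {
    stop_schema(sprintf("centroid file lacks field(s): %s", paste(miss, collapse = ", ")))
  }
  variant <- obj$variant
  feats <- unlist(obj$feature_names)
  expected <- variant_features(variant)
  if (!identical(sort(feats), sort(expected))) {
    stop_schema(sprintf(
      "variant '%s' requires features {%s}, file declares {%s}",
      variant, paste(expected, collapse = ", "), paste(feats, collapse = ", ")
    ))
  }
  standardization <- tibble::tibble(
    feature = feats,
    mean = as.numeric(unlist(obj$mean[feats])),
    sd = as.numeric(unlist(obj$sd[feats]))
  )
  if (any(!is.finite(standardization$sd)) || any(standardization$sd <= 0)) {
    stop_schema("all standardization SDs must be finite and > 0")
  }
  if (!identical(sort(names(obj$centroids)), sort(subtype_levels()))) {
    stop_schema("centroid file must define exactly SIDD, SIRD, MOD, MARD")
  }
  centers <- t(vapply(
    subtype_levels(),
    function(s) as.numeric(unlist(obj$centroids[[s]][feats])),
    numeric(length(feats))
  ))
  colnames(centers) <- feats
  new_subtype_centroids(variant, feats, standardization, centers,
    provenance = "loaded_from_file"
  )
}

#' Assign diabetes subtypes by the nearest-centroid rule
#'
#' GADA-positive individuals are assigned to SAID outright (autoimmune
#' diabetes is gated out before clustering). Everyone else is assigned to
#' the subtype whose centroid is nearest in Euclidean distance after
#' z-scoring the features with the centroids' frozen standardization
#' parameters. Exact distance ties are broken deterministically in the
#' order SIDD, SIRD, MOD, MARD.
#'
#' @param features Data frame with the variant's feature columns; may also
#'   carry `participant_id` and a logical `gada_positive` column (assumed
#'   `FALSE` when absent).
#' @param centroids A `subtype_centroids` object.
#' @return A tibble with `participant_id` (if supplied), `subtype`, and one
#'   `dist_*` column per centroid (`NA` for SAID rows).
#' @export
assign_subtype <- function(features, centroids) {
  stopifnot(inherits(centroids, "subtype_centroids"))
  feats <- centroids$feature_names
  missing <- setdiff(feats, names(features))
  if (length(missing) > 0) {
    stop_classification(sprintf(
      "missing classification feature(s): %s", paste(missing, collapse = ", ")
    ))
  }
  gada <- if ("gada_positive" %in% names(features)) {
    features$gada_positive
  } else {
    rep(FALSE, nrow(features))
  }
  bad <- !gada & !complete.cases(features[, feats, drop = FALSE])
  if (any(bad)) {
    stop_classification(sprintf(
      "missing feature values in %d row(s) of GADA-negative input", sum(bad)
    ))
  }
  out <- tibble::tibble(.rows = nrow(features))
  if ("participant_id" %in% names(features)) {
    out$participant_id <- features$participant_id
  }
  dist_cols <- paste0("dist_", subtype_levels())
  dmat <- matrix(NA_real_,
    nrow = nrow(features), ncol = 4,
    dimnames = list(NULL, dist_cols)
  )
  subtype <- rep("SAID", nrow(features))
  neg <- which(!gada)
  if (length(neg) > 0) {
    z <- standardize(features[neg, feats, drop = FALSE], centroids$standardization)
    cen <- centroids$centroids[subtype_levels(), , drop = FALSE]
    for (k in seq_len(4)) {
      dmat[neg, k] <- sqrt(rowSums(
        (z - matrix(cen[k, ], nrow = length(neg), ncol = ncol(z), byrow = TRUE))^2
      ))
    }
    # which.min returns the first minimum: the SIDD < SIRD < MOD < MARD
    # tie-break order falls out of the fixed column order
    subtype[neg] <- subtype_levels()[apply(dmat[neg, , drop = FALSE], 1, which.min)]
  }
  out$subtype <- subtype
  out <- dplyr::bind_cols(out, tibble::as_tibble(dmat))
  out
}

#' Percent agreement between two subtype label vectors
#'
#' @param labels_a,labels_b Equal-length vectors of subtype labels from two
#'   classifier variants, aligned by participant.
#' @return An object of class `subtype_concordance`: a list with `agreement`
#'   (percent of identical pairs), `n`, and `confusion` (contingency table
#'   of a vs b).
#' @examples
#' concordance(c("SIDD", "MOD"), c("SIDD", "MARD"))$agreement # 50
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_contract("label vectors must have equal length")
  }
  levs <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  structure(
    list(
      agreement = 100 * mean(a == b),
      n = length(a),
      confusion = table(a = a, b = b)
    ),
    class = "subtype_concordance"
  )
}

#' @export
print.subtype_concordance <- function(x, ...) {
  cat(sprintf("Concordance: %.1f%% of %d pairs agree\n", x$agreement, x$n))
  print(x$confusion)
  invisible(x)
}
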