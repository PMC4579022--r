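#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: key-slice undersampling,
#' level-set solver settings, PCA retained variance, classifier choice and
#' hyperparameters, cross-validation shape and the region-detection
#' threshold.
#'
#' @param manifest Path to a cohort manifest CSV (columns `subject_id`,
#'   `path`, `label`, `cdr`; optional `age`, `sex`).
#' @param out_dir Output directory for reports.
#' @param keyslice_step Undersampling step of the key-slice rule.
#' @param levelset A [levelset_params()].
#' @param variance_fraction PCA retained-variance fraction.
#' @param classifier A [classifier_spec()] or classifier name.
#' @param K,repeats,seed Cross-validation folds, repetitions and seed.
#' @param region_T Displacement-magnitude threshold for region detection.
#' @param min_age Optional minimum age; manifest rows below it are dropped
#'   (subjects without an age column are kept).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = NULL,
                            keyslice_step = 10,
                            levelset = levelset_params(),
                            variance_fraction = 0.95,
                            classifier = "tsvm",
                            K = 10, repeats = 50, seed = 1L,
                            region_T = 5, min_age = NULL) {
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  stopifnot(inherits(levelset, "levelset_params"),
            inherits(classifier, "classifier_spec"))
  if (keyslice_step < 1 || K < 2 || repeats < 1 || region_T <= 0)
    stop("configuration value out of range", call. = FALSE)
  structure(list(manifest = manifest, out_dir = out_dir,
                 keyslice_step = as.integer(keyslice_step),
                 levelset = levelset,
                 variance_fraction = variance_fraction,
                 classifier = classifier,
                 K = as.integer(K), repeats = as.integer(repeats),
                 seed = as.integer(seed), region_T = region_T,
                 min_age = min_age), class = "pipeline_config")
}

#' Read and validate a cohort manifest CSV
#'
#' Labels are derived from the clinical dementia rating: CDR 1 maps to AD
#' (label 1) and CDR 0 to NC (label 0); any other CDR value is rejected
#' (such subjects are excluded upstream).
#'
#' @param path Manifest CSV path.
#' @param min_age Optional minimum age filter.
#' @return Data frame with at least `subject_id`, `path`, `label`, `cdr`.
#' @export
read_manifest <- function(path, min_age = NULL) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "cdr")
  if (!all(need %in% names(m)))
    stop("manifest must have columns subject_id, path, cdr", call. = FALSE)
  if (!all(m$cdr %in% c(0, 1)))
    stop("manifest contains CDR values other than {0, 1}; ",
         "such subjects must be excluded upstream", call. = FALSE)
  m$label <- as.integer(m$cdr)
  if (!is.null(min_age) && "age" %in% names(m))
    m <- m[is.na(m$age) | m$age >= min_age, , drop = FALSE]
  m
}

#' Load a cohort of NIfTI volumes as coronal slice stacks
#'
#' Volumes are read with RNifti; coronal slices are taken along the given
#' voxel axis (default the third, matching [write_cohort()]'s layout; use
#' 2 for canonically reoriented whole-head volumes).
#'
#' @param manifest Data frame from [read_manifest()] (or a manifest path).
#' @param coronal_axis Voxel axis indexed by the coronal slice number.
#' @return A `cohort_dataset`.
#' @export
load_cohort <- function(manifest, coronal_axis = 3) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- as.array(RNifti::readNifti(manifest$path[i]))
    if (length(dim(vol)) != 3)
      stop("expected a 3-D volume: ", manifest$path[i], call. = FALSE)
    nk <- dim(vol)[coronal_axis]
    images <- lapply(seq_len(nk), function(k) {
      sl <- switch(coronal_axis,
                   vol[k, , ], vol[, k, ], vol[, , k])
      as.matrix(sl)
    })
    list(id = as.character(manifest$subject_id[i]),
         label = as.integer(manifest$label[i]),
         cdr = manifest$cdr[i], images = images)
  })
  nk <- unique(vapply(subjects, function(s) length(s$images), integer(1)))
  if (length(nk) != 1)
    stop("subjects have differing coronal slice counts", call. = FALSE)
  structure(list(subjects = subjects, n_slices = nk,
                 slice_positions = seq(0, 1, length.out = nk),
                 spec = NULL), class = "cohort_dataset")
}

#' Run the full displacement-field morphometry pipeline
#'
#' Executes, in order: key-slice selection by inter-class variance,
#' displacement-field feature building against the mean-NC template, PCA +
#' classifier evaluation by repeated stratified cross-validation, and
#' region detection between the first NC and first AD subject. When
#' `config$out_dir` is set, writes `report.json`, `regions.csv`,
#' `keyslices.json` and a provenance record.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-loaded `cohort_dataset`; otherwise loaded
#'   from `config$manifest`.
#' @return List with `key_slices`, `features`, `report` (an
#'   `eval_report`) and `regions` (list of `region_set`).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("load", load_cohort(
      read_manifest(config$manifest, config$min_age)))
  y <- cohort_labels(cohort)
  key <- stage("keyslices", {
    curve <- icv_curve(cohort)
    step <- config$keyslice_step
    ks <- select_key_slices(curve, step = step)
    # fall back to the densest grid on short stacks so that downstream
    # stages always receive at least one slice
    while (length(ks$indices) == 0 && step > 1) {
      step <- max(1L, step %/% 2L)
      ks <- suppressWarnings(select_key_slices(curve, step = step))
    }
    ks
  })
  feats <- stage("features", build_features(
    cohort, key, params = config$levelset))
  report <- stage("evaluate", run_cv(
    feats, classifier = config$classifier, K = config$K,
    repeats = config$repeats, seed = config$seed,
    variance_fraction = config$variance_fraction))
  regions <- stage("regions", {
    nc <- which(y == 0)[1]
    ad <- which(y == 1)[1]
    run_region_detection(cohort, nc, ad, key, T = config$region_T,
                         params = config$levelset)
  })
  result <- list(key_slices = key, features = feats, report = report,
                 regions = regions)
  if (!is.null(config$out_dir)) write_pipeline_outputs(config, result)
  result
}

write_pipeline_outputs <- function(config, result) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- result$report
  jsonlite::write_json(list(
    classifier = rep$classifier, K = rep$K, repeats = rep$repeats,
    seed = rep$seed, mean = as.list(rep$mean), sd = as.list(rep$sd),
    per_repetition = as.data.frame(rep$per_repetition)
  ), file.path(config$out_dir, "report.json"),
  auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    indices = result$key_slices$indices,
    threshold = result$key_slices$threshold,
    undersampling = result$key_slices$undersampling
  ), file.path(config$out_dir, "keyslices.json"),
  auto_unbox = TRUE, digits = NA)
  write.csv(regions_to_df(result$regions),
            file.path(config$out_dir, "regions.csv"), row.names = FALSE)
  prov <- list(
    timestamp = format(Sys.time(), tz = "UTC"),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("dfmorph")),
    seed = config$seed,
    config = list(keyslice_step = config$keyslice_step,
                  levelset = unclass(config$levelset),
                  variance_fraction = config$variance_fraction,
                  classifier = config$classifier$name,
                  classifier_args = config$classifier$args,
                  K = config$K, repeats = config$repeats,
                  region_T = config$region_T))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
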