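#' Write a T x V series as a 4-D NIfTI volume
#'
#' Voxels are unflattened column-major (first grid index fastest), the
#' same fixed order used by [load_nifti_series()] and
#' [make_spatial_maps()].
#'
#' @param mat T x V matrix.
#' @param grid_shape length-3 grid dimensions with `prod == V`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size in millimetres.
#' @param tr repetition time in seconds, stored in the 4th pixdim slot.
#' @return the path, invisibly.
#' @export
write_nifti_series <- function(mat, grid_shape, path, voxel_mm = 3,
                               tr = 3) {
  mat <- as.matrix(mat)
  stopifnot(length(grid_shape) == 3L, prod(grid_shape) == ncol(mat))
  arr <- array(t(mat), c(grid_shape, nrow(mat)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(rep(voxel_mm, 3), tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a 4-D NIfTI volume as a T x V matrix
#'
#' Flattens each volume column-major (first grid index fastest); with a
#' mask, only in-mask voxels are kept, in the same fixed order.
#'
#' @param path 4-D NIfTI file.
#' @param mask optional 3-D logical/integer array or NIfTI path matching
#'   the data grid.
#' @return T x V matrix with attributes `geometry` (list with `dim`,
#'   `pixdim`) and `mask_index` (voxel indices kept).
#' @export
load_nifti_series <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D image, got ", length(dim(arr)), " dimensions")
  d <- dim(arr)
  V <- prod(d[1:3])
  mat <- t(matrix(arr, V, d[4L]))
  keep <- seq_len(V)
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
    if (!identical(dim(mask)[1:3], d[1:3]))
      stop("geometry conflict: mask grid ",
           paste(dim(mask), collapse = "x"), " does not match data grid ",
           paste(d[1:3], collapse = "x"))
    keep <- which(as.logical(mask))
    mat <- mat[, keep, drop = FALSE]
  }
  attr(mat, "geometry") <- list(dim = d[1:3],
                                pixdim = RNifti::pixdim(img))
  attr(mat, "mask_index") <- keep
  mat
}

#' Write component maps as a 4-D NIfTI (one volume per component)
#'
#' @param maps K x V matrix.
#' @param grid_shape length-3 grid dimensions.
#' @param path output file.
#' @param voxel_mm voxel size in millimetres.
#' @return the path, invisibly.
#' @export
write_nifti_maps <- function(maps, grid_shape, path, voxel_mm = 3) {
  write_nifti_series(maps, grid_shape, path, voxel_mm = voxel_mm, tr = 1)
}

#' Read a subject label table
#'
#' Tab-separated file with at least `subject_id` and `group` columns.
#'
#' @param path TSV file.
#' @return data.frame with `subject_id` (character) and `group` (factor).
#' @export
load_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("label table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  tab$group <- factor(tab$group)
  tab
}

.FEATURE_FORMAT <- "dfclstm-features"
.FEATURE_VERSION <- 1L

#' Save a set of feature sequences or vectors
#'
#' Serialised archive with a versioned header and metadata describing the
#' feature space (level, K, window width/step, tr), so a model trained on
#' one archive can refuse mismatched features.
#'
#' @param features named list of per-subject feature objects, or a
#'   subjects x d matrix of static features.
#' @param path output file (`.rds`).
#' @param metadata named list (e.g. `level`, `K`, `width`, `step`, `tr`).
#' @return the path, invisibly.
#' @export
save_features <- function(features, path, metadata = list()) {
  saveRDS(list(format = .FEATURE_FORMAT, version = .FEATURE_VERSION,
               metadata = metadata, features = features), path)
  invisible(path)
}

#' Load a feature archive written by [save_features()]
#'
#' @param path archive file.
#' @return list with `features` and `metadata`.
#' @export
load_features <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, .FEATURE_FORMAT))
    stop("not a feature archive: ", path)
  if (obj$version > .FEATURE_VERSION)
    stop("feature archive version ", obj$version,
         " is newer than supported (", .FEATURE_VERSION, ")")
  obj[c("features", "metadata")]
}

#' Write a synthetic cohort to disk
#'
#' Per-subject 4-D NIfTI volumes (or a single serialised archive), a
#' tab-separated label table, and the ground truth (maps, state
#' sequences, covariances) as a separate archive.
#'
#' @param cohort a [make_cohort()] object.
#' @param dir output directory (created if needed).
#' @param format `"nifti"` for per-subject volumes or `"archive"` for a
#'   single `cohort.rds`.
#' @param tr repetition time stored with NIfTI output.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "archive"),
                         tr = 3) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort[c("maps", "covariances", "state_sequences",
                    "effect_pairs", "effect_states", "delta", "snr",
                    "grid_shape", "seed")]
  saveRDS(truth, file.path(dir, "ground_truth.rds"))
  if (format == "nifti") {
    for (i in seq_len(nrow(cohort$labels)))
      write_nifti_series(cohort$voxels[[i]], cohort$grid_shape,
                         file.path(dir, paste0(cohort$labels$subject_id[i],
                                               "_bold.nii.gz")), tr = tr)
  } else {
    saveRDS(cohort, file.path(dir, "cohort.rds"))
  }
  invisible(dir)
}

#' Default pipeline configuration
#'
#' The defaults encode the pipeline's standard settings: 20 group ICA
#' components with 10 ICASSO runs, sliding windows of width 50 TR and
#' step 1 TR, a 0.01-0.08 Hz pass band, and 10-fold cross-validation.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    paths = list(data = NULL, atlas = NULL, output = NULL),
    ica = list(n_components = 20L, icasso_runs = 10L, keep_list = NULL,
               variance_threshold = 0.95, subject_cap = 30L),
    windows = list(width = 50L, step = 1L),
    band = c(0.01, 0.08),
    tr = 3,
    classifier = list(type = "lstm", hidden = 30L, fc = 16L, lr = 1e-3,
                      epochs = 200L, batch_size = 16L, patience = 25L),
    cv = list(k = 10L, seed = 1L),
    level = "ica",
    mode = "dynamic"
  )
}

## Recursive merge of user values into defaults; unknown keys rejected.
.merge_config <- function(defaults, user, prefix = "") {
  for (nm in names(user)) {
    key <- paste0(prefix, nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", key, " must be a mapping")
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(key, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Parse and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; omitted keys fall back to
#' [default_config()] values, and each applied default is reported via
#' `message()`.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return validated configuration list.
#' @export
parse_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(defaults, user)
  flat_d <- unlist(defaults)
  flat_u <- unlist(user)
  defaulted <- setdiff(names(flat_d), names(flat_u))
  if (length(defaulted))
    message("using defaults for: ", paste(defaulted, collapse = ", "))
  stopifnot(cfg$windows$width >= 2, cfg$windows$step >= 1,
            cfg$cv$k >= 2, cfg$ica$n_components >= 1)
  if (!cfg$level %in% c("ica", "roi", "truth"))
    stop("level must be one of ica/roi/truth")
  if (!cfg$mode %in% c("dynamic", "static"))
    stop("mode must be dynamic or static")
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration (and its hash), seeds, package and R
#' versions, and any collected warnings — enough to rerun the
#' deterministic stages bit-exactly.
#'
#' @param path output JSON file.
#' @param config configuration list.
#' @param seeds named list/vector of seeds used.
#' @param warnings character vector of collected warnings.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, seeds, warnings = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dfclstm")),
    r_version = R.version.string,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seeds = seeds,
    warnings = warnings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
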