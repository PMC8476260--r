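#' Pipeline configuration
#'
#' @param k number of atlases to select (default 10).
#' @param side which foramen-like structure to segment: `"left"` or
#'   `"right"`.
#' @param fusion fusion method: `"staple"`, `"mv"` or `"simple"`.
#' @param registration a [registration_config()].
#' @param fusion_params named list of extra arguments for the fusion method
#'   (e.g. `tol`, `max_iter` for STAPLE; `alpha`, `min_keep` for SIMPLE).
#' @param seed master seed; per-atlas registration seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 10L, side = c("left", "right"),
                            fusion = c("staple", "mv", "simple"),
                            registration = registration_config(),
                            fusion_params = list(), seed = 42L) {
  side <- match.arg(side)
  fusion <- match.arg(fusion)
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), side = side, fusion = fusion,
                 registration = registration, fusion_params = fusion_params,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; a `registration:` block mirrors
#' [registration_config()] (including `preset: desk|paper`).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  reg <- do.call(registration_config, y$registration %||% list())
  args <- y[setdiff(names(y), "registration")]
  do.call(pipeline_config, c(args, list(registration = reg)))
}

# atlas directory convention: <id>_gray.<ext> + <id>_label_<side>.<ext>;
# a manifest.csv (from make_cohort) restricts to role == "atlas"
load_atlas_dir <- function(dir, side) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    man <- man[man$role == "atlas", , drop = FALSE]
    ids <- man$id
    grays <- file.path(dir, man$gray)
    labels <- file.path(dir, man[[paste0("label_", side)]])
  } else {
    grays <- sort(list.files(dir, "_gray\\.(nii(\\.gz)?|mha)$",
                             full.names = TRUE))
    ids <- sub("_gray\\.(nii(\\.gz)?|mha)$", "", basename(grays))
    labels <- vapply(ids, function(id) {
      cand <- list.files(dir, paste0("^", id, "_label_", side,
                                     "\\.(nii(\\.gz)?|mha)$"),
                         full.names = TRUE)
      if (!length(cand)) stop("no ", side, " label found for atlas ", id,
                              call. = FALSE)
      cand[1]
    }, character(1))
  }
  if (!length(ids)) stop("no atlases found in ", dir, call. = FALSE)
  lapply(seq_along(ids), function(i)
    atlas(ids[i], read_volume(grays[i]), read_labelmap(labels[i])))
}

register_one <- function(fixed, gray, regcfg, seed) {
  regcfg$rng_seed <- as.integer(seed %% .Machine$integer.max)
  aff <- register_affine(fixed, gray, regcfg)
  ffd <- register_bspline(fixed, gray, aff, regcfg)
  transform_chain(aff, ffd)
}

fuse_stack <- function(stack, method, params = list()) {
  switch(method,
         mv = majority_vote(stack),
         staple = do.call(staple, c(list(stack), params)),
         simple = do.call(simple_fuse, c(list(stack), params)),
         stop("unknown fusion method: ", method, call. = FALSE))
}

#' Multi-atlas segmentation of one target volume
#'
#' Runs the full pipeline on `fixed`: rank all atlases by NCC, select the top
#' `k`, register each (multiresolution affine then B-spline FFD), propagate
#' the atlas labels with nearest-neighbor interpolation, and fuse them.
#'
#' @param fixed the target [volume()].
#' @param atlas_dir directory of atlas pairs
#'   (`<id>_gray.nii.gz` + `<id>_label_<side>.nii.gz`, or a
#'   `manifest.csv` from [make_cohort()]).
#' @param cfg a [pipeline_config()].
#' @return List with `label` (the fused [labelmap()] on the fixed grid) and
#'   `record` (a run record: ranking, selected ids, transforms, per-stage
#'   timings, fusion audit; serializable with [write_run_record()]).
#' @export
segment <- function(fixed, atlas_dir, cfg = pipeline_config()) {
  stopifnot(inherits(fixed, "volume"))
  t0 <- proc.time()[["elapsed"]]
  atlases <- load_atlas_dir(atlas_dir, cfg$side)
  ranked <- rank_atlases(fixed, atlases)
  sel <- select_top_k(ranked, cfg$k)
  byid <- stats::setNames(atlases, vapply(atlases, `[[`, character(1), "id"))
  t1 <- proc.time()[["elapsed"]]
  chains <- list()
  labels <- list()
  for (i in seq_along(sel)) {
    a <- byid[[sel[i]]]
    chains[[a$id]] <- register_one(fixed, a$gray, cfg$registration,
                                   cfg$seed + i)
    labels[[a$id]] <- warp_label(a$label, chains[[a$id]], fixed)
  }
  t2 <- proc.time()[["elapsed"]]
  stack <- decision_stack(labels, names(labels))
  fr <- fuse_stack(stack, cfg$fusion, cfg$fusion_params)
  t3 <- proc.time()[["elapsed"]]
  record <- list(
    selection = ranked, selected = sel, fusion = cfg$fusion,
    k = cfg$k, side = cfg$side, seed = cfg$seed,
    preset = cfg$registration$preset,
    transforms = lapply(chains, transform_to_list),
    fusion_audit = fr$audit, performance = fr$performance,
    foreground_voxels = sum(fr$fused$voxels),
    timings = c(selection = t1 - t0, registration = t2 - t1,
                fusion = t3 - t2))
  list(label = fr$fused, record = record)
}

#' Serialize a run record to JSON
#'
#' @param record the `record` element returned by [segment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  invisible(path)
}

#' Benchmark all fusion methods on a phantom cohort
#'
#' For every test member of a cohort directory (see [make_cohort()]) and both
#' sides, registers the `k` NCC-selected atlases once, propagates left and
#' right labels through the same transforms, fuses with MV, STAPLE and
#' SIMPLE, and evaluates each result against the ground truth.
#'
#' @param cohort_dir directory written by [make_cohort()] (must contain
#'   `manifest.csv` with atlas and test members and truth labels).
#' @param cfg a [pipeline_config()] (its `side`/`fusion` fields are ignored;
#'   all combinations run).
#' @param out_dir optional directory for `results.csv` (one row per case,
#'   side and method — the per-case layout behind the summary tables and box
#'   plots) and `means.csv`.
#' @return List with `results` (one row per case x side x method: `case_id`,
#'   `side`, `method`, `dice`, `hd95_mm`, `asd_mm`, `error`) and `means`
#'   (per method x side averages).
#' @export
run_benchmark <- function(cohort_dir, cfg = pipeline_config(),
                          out_dir = NULL) {
  mf <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", cohort_dir, call. = FALSE)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  tests <- man[man$role == "test", , drop = FALSE]
  if (!nrow(tests)) stop("cohort has no test members", call. = FALSE)
  atlasL <- load_atlas_dir(cohort_dir, "left")
  atlasR <- load_atlas_dir(cohort_dir, "right")
  idsA <- vapply(atlasL, `[[`, character(1), "id")
  rows <- list()
  for (ti in seq_len(nrow(tests))) {
    case_id <- tests$id[ti]
    res <- tryCatch({
      fixed <- read_volume(file.path(cohort_dir, tests$gray[ti]))
      truth <- list(left = read_labelmap(file.path(cohort_dir,
                                                   tests$label_left[ti])),
                    right = read_labelmap(file.path(cohort_dir,
                                                    tests$label_right[ti])))
      ranked <- rank_atlases(fixed, atlasL)
      sel <- select_top_k(ranked, cfg$k)
      stacks <- list(left = list(), right = list())
      for (i in seq_along(sel)) {
        ai <- match(sel[i], idsA)
        chain <- register_one(fixed, atlasL[[ai]]$gray, cfg$registration,
                              cfg$seed + 1009L * ti + i)
        stacks$left[[sel[i]]] <- warp_label(atlasL[[ai]]$label, chain, fixed)
        stacks$right[[sel[i]]] <- warp_label(atlasR[[ai]]$label, chain, fixed)
      }
      out <- list()
      for (side in c("left", "right")) {
        stk <- decision_stack(stacks[[side]], names(stacks[[side]]))
        for (method in c("mv", "staple", "simple")) {
          fr <- fuse_stack(stk, method)
          ev <- evaluate(fr$fused, truth[[side]])
          out[[paste(side, method)]] <-
            data.frame(case_id = case_id, side = side, method = method,
                       dice = ev$dice, hd95_mm = ev$hd95_mm,
                       asd_mm = ev$asd_mm, error = NA_character_,
                       stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out)
    }, error = function(e) {
      warning("case ", case_id, " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(case_id = case_id, side = NA_character_,
                 method = NA_character_, dice = NA_real_, hd95_mm = NA_real_,
                 asd_mm = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[ti]] <- res
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- results[is.na(results$error), , drop = FALSE]
  means <- stats::aggregate(ok[c("dice", "hd95_mm", "asd_mm")],
                            by = list(method = ok$method, side = ok$side),
                            FUN = mean, na.rm = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(means, file.path(out_dir, "means.csv"),
                     row.names = FALSE)
  }
  list(results = results, means = means)
}
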