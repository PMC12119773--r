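#' @include AllClasses.R io.R phantom.R projection.R preprocess.R augment.R
#' @include segmentation.R localization.R classification.R ensemble.R
#' @include explain.R
NULL

#' Pipeline configuration
#'
#' Validated, schema-versioned parameter set for [runPipeline()]. All
#' cross-stage constants (pixel spacing, crop margins) live in one place.
#'
#' @slot config named list of stage parameters.
#' @export
setClass("PipelineConfig", representation(config = "list"))

.default_pipeline_config <- function(workdir = "scintigrade-run", seed = 1L) {
  list(
    schema_version = 1L,
    workdir = workdir,
    seed = as.integer(seed),
    spacing_mm = 2.8,
    phantom = list(grid_shape = c(96L, 96L, 96L),
                   total_counts_per_view = 2e6, dilate_mm = 2),
    segdata = list(n_patients = 6L, augment_min = 0.3, augment_step = 0.3,
                   augment_levels = 5L),
    cohort = list(n_patients = 12L,
                  grade_proportions = c(0.25, 0.25, 0.25, 0.25)),
    augment = list(min_fraction = 0.05, max_fraction = 1.5, step = 0.05,
                   n_augmented_per_case = 28L),
    segmentation = list(patch_hw = c(96L, 96L), epochs = 6L, batch_size = 2L,
                        lr0 = 1e-2, patches_per_image = 8L),
    localization = list(margins_mm = list(lv = 70, whole_heart = 50,
                                          ribcage = 1)),
    classification = list(folds = 3L, tasks = c("detection", "severity"),
                          epochs = 15L, batch_size = 2L, lr0 = 3e-3,
                          input_hw = c(64L, 64L), balance = TRUE),
    explain = list(n_cases = 2L, occlusion_patch = c(16L, 16L),
                   occlusion_stride = 8L, threshold = 0.5)
  )
}

.check_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop("config key ", path, nm,
                                    " must be a mapping")
      .check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.validate_pipeline_config <- function(cfg) {
  if (!identical(as.integer(cfg$schema_version), 1L))
    stop("unsupported config schema_version: ", cfg$schema_version)
  if (cfg$spacing_mm <= 0) stop("spacing_mm must be positive")
  mm <- cfg$localization$margins_mm
  if (!all(c("lv", "whole_heart", "ribcage") %in% names(mm)))
    stop("localization.margins_mm must name lv, whole_heart and ribcage")
  if (any(unlist(mm) < 0)) stop("crop margins must be >= 0")
  if (abs(sum(cfg$cohort$grade_proportions) - 1) > 1e-9)
    stop("cohort.grade_proportions must sum to 1")
  if (cfg$classification$folds < 2) stop("classification.folds must be >= 2")
  invisible(cfg)
}

#' Build or read a [PipelineConfig-class]
#'
#' `pipelineConfig()` merges overrides into the package defaults;
#' `readPipelineConfig()` reads a YAML file. Unknown keys are rejected and
#' cross-stage consistency (spacing, margins, proportions) is validated.
#'
#' @param workdir working directory for all pipeline artifacts.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param ... named overrides of the default keys (nested lists).
#' @return a `PipelineConfig`.
#' @export
pipelineConfig <- function(workdir = "scintigrade-run", seed = 1L, ...) {
  base <- .default_pipeline_config(workdir, seed)
  override <- list(...)
  .check_keys(override, base)
  cfg <- .merge_config(base, override)
  .validate_pipeline_config(cfg)
  new("PipelineConfig", config = cfg)
}

#' @rdname pipelineConfig
#' @param path YAML file with (a subset of) the config keys.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- .default_pipeline_config()
  .check_keys(raw, base)
  cfg <- .merge_config(base, raw)
  .validate_pipeline_config(cfg)
  new("PipelineConfig", config = cfg)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig (schema", object@config$schema_version, ") workdir:",
      object@config$workdir, "seed:", object@config$seed, "\n")
})

## -------------------------------------------------------------- manifests ----

.config_md5 <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

.write_manifest <- function(cfg, stage, inputs, outputs) {
  mdir <- file.path(cfg$workdir, "manifests")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  git <- tryCatch(
    system2("git", c("describe", "--always", "--dirty"), stdout = TRUE,
            stderr = FALSE)[1],
    error = function(e) NA_character_, warning = function(w) NA_character_)
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("scintigrade")),
              seed = cfg$seed,
              config_md5 = .config_md5(cfg),
              config = cfg,
              git_describe = git,
              inputs = lapply(inputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))),
              outputs = lapply(outputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, file.path(mdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the '", producer,
         "' stage first")
  path
}

## ----------------------------------------------------------------- stages ----

.stage_simulate <- function(cfg) {
  spec <- PhantomSpec(gridShape = cfg$phantom$grid_shape,
                      spacingMm = cfg$spacing_mm)
  seg <- generateCohort(cfg$segdata$n_patients, c(1, 0, 0, 0), spec,
                        seed = cfg$seed,
                        totalCountsPerView = cfg$phantom$total_counts_per_view,
                        dilateMm = cfg$phantom$dilate_mm)
  coh <- generateCohort(cfg$cohort$n_patients, cfg$cohort$grade_proportions,
                        spec, seed = cfg$seed + 1L,
                        totalCountsPerView = cfg$phantom$total_counts_per_view,
                        dilateMm = cfg$phantom$dilate_mm)
  writeCohort(seg, file.path(cfg$workdir, "segdata"), seed = cfg$seed)
  writeCohort(coh, file.path(cfg$workdir, "cohort"), seed = cfg$seed + 1L)
  vdir <- file.path(cfg$workdir, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  ph <- generatePhantom(PhantomSpec(gridShape = cfg$phantom$grid_shape,
                                    spacingMm = cfg$spacing_mm,
                                    seed = cfg$seed))
  writeVolume(ph$volume, file.path(vdir, "example.nii.gz"))
  .write_manifest(cfg, "simulate", character(),
                  c(file.path(cfg$workdir, "segdata", "labels.csv"),
                    file.path(cfg$workdir, "cohort", "labels.csv"),
                    file.path(vdir, "example.nii.gz")))
}

.stage_project <- function(cfg) {
  vdir <- file.path(cfg$workdir, "volumes")
  .require_artifact(vdir, "simulate")
  vols <- list.files(vdir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  pdir <- file.path(cfg$workdir, "projected")
  dir.create(pdir, showWarnings = FALSE)
  outs <- character()
  for (v in vols) {
    img <- projectVolume(readVolume(v))
    out <- file.path(pdir, sub("\\.nii(\\.gz)?$", "_pseudo.nii.gz",
                               basename(v)))
    writePlanar(img, out)
    outs <- c(outs, out)
  }
  .write_manifest(cfg, "project", vols, outs)
}

.stage_augment <- function(cfg) {
  sdir <- .require_artifact(file.path(cfg$workdir, "segdata"), "simulate")
  cases <- readCohort(sdir)
  scheme <- UptakeLevelScheme(
    minFraction = cfg$segdata$augment_min,
    maxFraction = cfg$segdata$augment_min +
      cfg$segdata$augment_step * (cfg$segdata$augment_levels - 1L),
    step = cfg$segdata$augment_step,
    nAugmentedPerCase = cfg$segdata$augment_levels)
  out <- list()
  for (cs in cases) {
    augs <- expandCase(caseImages(cs)$anterior, caseMasks(cs)$lv, scheme,
                       seed = cfg$seed + caseGrade(cs) + 7L)
    for (j in seq_along(augs)) {
      aid <- sprintf("%s_f%03.0f", acquisitionId(cs),
                     100 * augs[[j]]@fraction)
      out[[length(out) + 1L]] <- LabeledCase(
        patientId(cs), aid, caseGrade(cs),
        images = list(anterior = augs[[j]]@image),
        uptakeFraction = augs[[j]]@fraction, masks = caseMasks(cs))
    }
  }
  writeCohort(out, file.path(cfg$workdir, "segdata_aug"), seed = cfg$seed)
  .write_manifest(cfg, "augment",
                  file.path(sdir, "labels.csv"),
                  file.path(cfg$workdir, "segdata_aug", "labels.csv"))
}

.stage_train_seg <- function(cfg) {
  adir <- .require_artifact(file.path(cfg$workdir, "segdata_aug"), "augment")
  cases <- readCohort(adir)
  mdir <- file.path(cfg$workdir, "models")
  dir.create(mdir, showWarnings = FALSE)
  patients <- unique(vapply(cases, patientId, character(1)))
  val_p <- patients[seq_len(max(1L, length(patients) %/% 4L))]
  outs <- character()
  for (s in .STRUCTURES) {
    pairs <- segmentationPairs(cases, s, views = "anterior")
    pid_of <- vapply(cases, patientId, character(1))
    val <- pairs[pid_of %in% val_p]
    tr <- pairs[!pid_of %in% val_p]
    segcfg <- SegTrainConfig(
      patchHw = cfg$segmentation$patch_hw,
      epochs = cfg$segmentation$epochs,
      batchSize = cfg$segmentation$batch_size,
      lr0 = cfg$segmentation$lr0,
      patchesPerImage = cfg$segmentation$patches_per_image,
      seed = cfg$seed + match(s, .STRUCTURES))
    fit <- trainSegmenter(tr, val, segcfg)
    mfile <- file.path(mdir, paste0("seg_", s, ".rds"))
    saveRDS(fit$model, mfile)
    write.csv(fit$history,
              file.path(mdir, paste0("seg_", s, "_history.csv")),
              row.names = FALSE)
    outs <- c(outs, mfile)
  }
  .write_manifest(cfg, "train-seg", file.path(adir, "labels.csv"), outs)
}

.pipeline_views <- c("anterior", "posterior", "summation")

.case_view_image <- function(cs, v) {
  if (v == "summation") {
    makeSummation(caseImages(cs)$anterior, caseImages(cs)$posterior)
  } else {
    caseImages(cs)[[v]]
  }
}

.stage_segment <- function(cfg) {
  cdir <- .require_artifact(file.path(cfg$workdir, "cohort"), "simulate")
  models <- lapply(.STRUCTURES, function(s) {
    readRDS(.require_artifact(
      file.path(cfg$workdir, "models", paste0("seg_", s, ".rds")),
      "train-seg"))
  })
  names(models) <- .STRUCTURES
  cases <- readCohort(cdir)
  pdir <- file.path(cfg$workdir, "predmasks")
  dir.create(pdir, showWarnings = FALSE)
  outs <- character()
  for (cs in cases) {
    for (v in .pipeline_views) {
      img <- .case_view_image(cs, v)
      # posterior views are mirror-standardized into the anterior frame for
      # the (anterior-trained, position-aware) segmenters, and the predicted
      # mask mirrored back
      seg_img <- if (v == "posterior") {
        PlanarImage(mirror_lr(pixels(img)), spacingMm(img), "anterior",
                    patientId(cs), acquisitionId(cs))
      } else img
      for (s in .STRUCTURES) {
        m <- slidingWindowSegment(models[[s]], seg_img,
                                  cfg$segmentation$patch_hw)
        if (v == "posterior") {
          m <- LabelMask(mirror_lr(m@data), m@structure, m@spacingMm)
        }
        fn <- file.path(pdir, sprintf("%s_%s_%s.nii.gz", patientId(cs), v, s))
        writePlanar(PlanarImage(m@data, m@spacingMm, img@view,
                                patientId(cs), acquisitionId(cs)), fn)
        outs <- c(outs, fn)
      }
    }
  }
  .write_manifest(cfg, "segment", file.path(cdir, "labels.csv"),
                  utils::head(outs, 9))
}

.stage_crop <- function(cfg) {
  cdir <- .require_artifact(file.path(cfg$workdir, "cohort"), "simulate")
  pdir <- .require_artifact(file.path(cfg$workdir, "predmasks"), "segment")
  cases <- readCohort(cdir)
  odir <- file.path(cfg$workdir, "crops")
  dir.create(odir, showWarnings = FALSE)
  margins <- unlist(cfg$localization$margins_mm)
  outs <- character()
  for (cs in cases) {
    for (v in .pipeline_views) {
      img <- .case_view_image(cs, v)
      masks <- list()
      for (s in .STRUCTURES) {
        fn <- file.path(pdir, sprintf("%s_%s_%s.nii.gz", patientId(cs), v, s))
        mi <- readPlanar(.require_artifact(fn, "segment"))
        masks[[s]] <- LabelMask(pixels(mi), s, spacingMm(mi))
      }
      crops <- localizeAll(img, masks, margins)
      for (s in names(crops)) {
        fn <- file.path(odir, sprintf("%s_%s_%s.nii.gz", patientId(cs), v, s))
        writePlanar(crops[[s]]$image, fn)
        outs <- c(outs, fn)
      }
    }
  }
  .write_manifest(cfg, "crop", file.path(cdir, "labels.csv"),
                  utils::head(outs, 9))
}

.crop_samples <- function(cfg, cases, task) {
  odir <- file.path(cfg$workdir, "crops")
  out <- list()
  for (cs in cases) {
    for (v in .pipeline_views) {
      for (s in .STRUCTURES) {
        fn <- .require_artifact(
          file.path(odir, sprintf("%s_%s_%s.nii.gz", patientId(cs), v, s)),
          "crop")
        out[[length(out) + 1L]] <- list(
          image = readPlanar(fn), pid = patientId(cs), view = v, crop = s,
          grade = caseGrade(cs),
          label = assignTaskLabel(caseGrade(cs), task))
      }
    }
  }
  out
}

.stage_train_cls <- function(cfg) {
  cdir <- .require_artifact(file.path(cfg$workdir, "cohort"), "simulate")
  cases <- readCohort(cdir)
  folds <- patientwiseFolds(cases, cfg$classification$folds,
                            seed = cfg$seed + 11L)
  mdir <- file.path(cfg$workdir, "models")
  dir.create(mdir, showWarnings = FALSE)
  outs <- character()
  for (tn in cfg$classification$tasks) {
    task <- TaskSpec(tn)
    samples <- .crop_samples(cfg, cases, task)
    plabel <- vapply(cases, function(cs)
      assignTaskLabel(caseGrade(cs), task), integer(1))
    names(plabel) <- vapply(cases, patientId, character(1))
    for (fd in seq_len(cfg$classification$folds)) {
      train_p <- names(folds)[folds != fd]
      # label-stratified 80/20 patient-wise validation split so both sets
      # keep both classes; a class with a single training patient is shared
      # between train and validation (checkpoint selection only) rather
      # than lost from either set
      val_p <- with_seed(cfg$seed + 13L + fd, {
        unlist(lapply(split(train_p, plabel[train_p]), function(g) {
          if (length(g) == 1L) g
          else sample(g, min(length(g) - 1L, max(1L, round(0.2 * length(g)))))
        }))
      })
      shared <- names(table(plabel[train_p]))[table(plabel[train_p]) == 1L]
      keep_in_train <- val_p[plabel[val_p] %in% shared]
      for (s in .STRUCTURES) {
        for (v in .pipeline_views) {
          sub <- Filter(function(x) x$crop == s && x$view == v, samples)
          tr <- Filter(function(x)
            x$pid %in% setdiff(train_p, setdiff(val_p, keep_in_train)), sub)
          va <- Filter(function(x) x$pid %in% val_p, sub)
          if (isTRUE(cfg$classification$balance)) {
            tr <- balanceClasses(tr, max(table(vapply(tr, function(x)
              x$label, integer(1)))), seed = cfg$seed + fd)
          }
          clscfg <- ClsTrainConfig(
            epochs = cfg$classification$epochs,
            batchSize = cfg$classification$batch_size,
            lr0 = cfg$classification$lr0,
            inputSpacingMm = cfg$spacing_mm,
            inputHw = cfg$classification$input_hw,
            seed = cfg$seed + 17L * fd + match(s, .STRUCTURES))
          fit <- trainClassifier(tr, va, task, clscfg, fold = fd, crop = s,
                                 view = v)
          mfile <- file.path(mdir, sprintf("cls_%s_f%d_%s_%s.rds", tn, fd,
                                           s, v))
          saveRDS(fit$model, mfile)
          outs <- c(outs, mfile)
        }
      }
    }
  }
  .write_manifest(cfg, "train-cls", file.path(cdir, "labels.csv"),
                  utils::head(outs, 9))
}

.stage_predict <- function(cfg) {
  cdir <- .require_artifact(file.path(cfg$workdir, "cohort"), "simulate")
  cases <- readCohort(cdir)
  folds <- patientwiseFolds(cases, cfg$classification$folds,
                            seed = cfg$seed + 11L)
  mdir <- file.path(cfg$workdir, "models")
  rows <- list()
  for (tn in cfg$classification$tasks) {
    task <- TaskSpec(tn)
    samples <- .crop_samples(cfg, cases, task)
    for (x in samples) {
      fd <- folds[[x$pid]]
      mfile <- .require_artifact(
        file.path(mdir, sprintf("cls_%s_f%d_%s_%s.rds", tn, fd, x$crop,
                                x$view)), "train-cls")
      model <- readRDS(mfile)
      p <- predictProba(model, x$image)
      rows[[length(rows) + 1L]] <- data.frame(
        task = tn, patient_id = x$pid, fold = fd, crop = x$crop,
        view = x$view, p0 = probs(p)[1], p1 = probs(p)[2],
        label = x$label, grade = x$grade)
    }
  }
  tab <- do.call(rbind, rows)
  out <- file.path(cfg$workdir, "predictions.csv")
  write.csv(tab, out, row.names = FALSE)
  .write_manifest(cfg, "predict", file.path(cdir, "labels.csv"), out)
}

.stage_ensemble <- function(cfg) {
  pred <- .require_artifact(file.path(cfg$workdir, "predictions.csv"),
                            "predict")
  tab <- read.csv(pred, colClasses = c(patient_id = "character"))
  rows <- list()
  for (tn in unique(tab$task)) {
    tt <- tab[tab$task == tn, ]
    for (pid in unique(tt$patient_id)) {
      tp <- tt[tt$patient_id == pid, ]
      members <- lapply(seq_len(nrow(tp)), function(i) {
        ClassProbabilities(c(tp$p0[i], tp$p1[i]), fold = tp$fold[i],
                           crop = tp$crop[i], view = tp$view[i])
      })
      ens <- twoStageEnsemble(members)
      rows[[length(rows) + 1L]] <- data.frame(
        task = tn, patient_id = pid, p0 = probs(averagedProbs(ens))[1],
        p1 = probs(averagedProbs(ens))[2],
        decision = ensembleDecision(ens), label = tp$label[1],
        grade = tp$grade[1])
    }
  }
  out <- file.path(cfg$workdir, "ensemble.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  .write_manifest(cfg, "ensemble", pred, out)
}

.stage_evaluate <- function(cfg) {
  ens <- .require_artifact(file.path(cfg$workdir, "ensemble.csv"),
                           "ensemble")
  tab <- read.csv(ens, colClasses = c(patient_id = "character"))
  mdir <- file.path(cfg$workdir, "metrics")
  dir.create(mdir, showWarnings = FALSE)
  outs <- character()
  for (tn in unique(tab$task)) {
    tt <- tab[tab$task == tn, ]
    probs_ <- lapply(seq_len(nrow(tt)), function(i)
      ClassProbabilities(c(tt$p0[i], tt$p1[i])))
    rep_ <- computeMetrics(tt$label, probs_)
    mj <- file.path(mdir, paste0(tn, ".json"))
    jsonlite::write_json(
      c(as.list(metricValues(rep_)),
        list(confusion = as.list(confusionCounts(rep_)))),
      mj, auto_unbox = TRUE, digits = NA)
    rc <- file.path(mdir, paste0("roc_", tn, ".csv"))
    write.csv(rocPoints(rep_), rc, row.names = FALSE)
    outs <- c(outs, mj, rc)
  }
  .write_manifest(cfg, "evaluate", ens, outs)
}

.stage_explain <- function(cfg) {
  cdir <- .require_artifact(file.path(cfg$workdir, "cohort"), "simulate")
  cases <- readCohort(cdir)
  folds <- patientwiseFolds(cases, cfg$classification$folds,
                            seed = cfg$seed + 11L)
  odir <- file.path(cfg$workdir, "explain")
  dir.create(odir, showWarnings = FALSE)
  tn <- cfg$classification$tasks[1]
  n <- min(cfg$explain$n_cases, length(cases))
  outs <- character()
  for (cs in cases[seq_len(n)]) {
    fd <- folds[[patientId(cs)]]
    model <- readRDS(.require_artifact(
      file.path(cfg$workdir, "models",
                sprintf("cls_%s_f%d_whole_heart_anterior.rds", tn, fd)),
      "train-cls"))
    crop <- readPlanar(.require_artifact(
      file.path(cfg$workdir, "crops",
                sprintf("%s_anterior_whole_heart.nii.gz", patientId(cs))),
      "crop"))
    inp <- prepareClassifierInput(crop, model$inputHw, model$inputSpacingMm)
    gc_ <- gradCAM(model, inp, targetClass = 1L)
    oc <- occlusionSensitivity(model, inp, targetClass = 1L,
                               patchHw = cfg$explain$occlusion_patch,
                               stride = cfg$explain$occlusion_stride)
    for (m in list(gc_, oc)) {
      fn <- file.path(odir, sprintf("%s_%s.nii.gz", patientId(cs),
                                    m@method))
      writePlanar(PlanarImage(m@values, spacingMm(inp), "pseudo",
                              patientId(cs), acquisitionId(cs)), fn)
      ov <- thresholdOverlay(m, cfg$explain$threshold)
      fo <- file.path(odir, sprintf("%s_%s_overlay.nii.gz", patientId(cs),
                                    m@method))
      writePlanar(PlanarImage(ov@data, spacingMm(inp), "pseudo",
                              patientId(cs), acquisitionId(cs)), fo)
      outs <- c(outs, fn, fo)
    }
  }
  .write_manifest(cfg, "explain", file.path(cdir, "labels.csv"), outs)
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`) of the simulation-to-evaluation pipeline
#' in the config's working directory. Every stage writes its artifacts plus
#' a JSON manifest (config hash, seed, input/output checksums) under
#' `workdir/manifests/`, so a finished run can be reproduced exactly from
#' its manifests.
#'
#' Stages: `simulate` (synthetic segmentation + graded cohorts), `project`
#' (pseudo-planar projection of stored volumes), `augment` (uptake expansion
#' of the segmentation cohort), `train-seg`, `segment`, `crop`, `train-cls`,
#' `predict` (per-model fold-wise probabilities), `ensemble` (two-stage
#' averaging), `evaluate` (metric reports + ROC tables), `explain` (GradCAM
#' and occlusion maps).
#'
#' @param config a [PipelineConfig-class].
#' @param command stage name or `"all"`.
#' @return invisibly, the config.
#' @export
runPipeline <- function(config, command = "all") {
  stopifnot(is(config, "PipelineConfig"))
  cfg <- config@config
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  stages <- c(simulate = .stage_simulate, project = .stage_project,
              augment = .stage_augment, `train-seg` = .stage_train_seg,
              segment = .stage_segment, crop = .stage_crop,
              `train-cls` = .stage_train_cls, predict = .stage_predict,
              ensemble = .stage_ensemble, evaluate = .stage_evaluate,
              explain = .stage_explain)
  if (identical(command, "all")) {
    for (nm in names(stages)) stages[[nm]](cfg)
  } else {
    if (!command %in% names(stages))
      stop("unknown command '", command, "'; available: all, ",
           paste(names(stages), collapse = ", "))
    stages[[command]](cfg)
  }
  invisible(config)
}
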