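#' @include AllClasses.R utils.R
NULL

# Ellipsoid indicator on normalized [0,1]^3 coordinates.
# ux, uy, uz are per-axis coordinate vectors; ctr/rad normalized triples.
.ellipsoid <- function(ux, uy, uz, ctr, rad) {
  q2 <- outer(outer((ux - ctr[1])^2 / rad[1]^2,
                    (uy - ctr[2])^2 / rad[2]^2, "+"),
              (uz - ctr[3])^2 / rad[3]^2, "+")
  q2 <= 1
}

# Elliptical cylinder along y: ellipse in the (x, z) plane, y within [y0, y1].
.cylinder_y <- function(ux, uy, uz, cx, cz, rx, rz, y0 = 0, y1 = 1) {
  exz <- outer((ux - cx)^2 / rx^2, (uz - cz)^2 / rz^2, "+") <= 1
  ysel <- uy >= y0 & uy <= y1
  out <- array(FALSE, c(length(ux), length(uy), length(uz)))
  for (j in which(ysel)) out[, j, ] <- exz
  out
}

#' Generate a digital thorax-abdomen-pelvis phantom
#'
#' Builds a parametric activity volume (soft tissue, rib/spine lattice, two
#' kidneys, bladder, cardiac blood pool) together with aligned `lv`,
#' `whole_heart` and `ribcage` masks. Organ positions, sizes and intensities
#' are jittered per phantom under the spec's seed, so a cohort of seeds gives
#' anatomically varied but reproducible patients.
#'
#' Left-ventricular uptake is added as a uniform activity inside the LV
#' shell, scaled so that the mean pseudo-planar (anterior-posterior summed)
#' contribution over the projected LV support equals
#' `cardiacUptakeFraction` times the 99th percentile of the baseline
#' (zero-uptake) projection. This reproduces the grading convention used for
#' the uptake augmentation: fraction 0 is a normal study, fractions near 1.5
#' a severe one.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([ActivityVolume-class]) and
#'   `anatomy` ([AnatomySet-class]).
#' @examples
#' ph <- generatePhantom(PhantomSpec(gridShape = 48, seed = 3))
#' dim(voxels(ph$volume))
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  gs <- spec@gridShape
  if (min(gs) < 32L)
    stop("grid too small to place organs: need at least 32 voxels per axis, got ",
         paste(gs, collapse = " x "))
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  ux <- (seq_len(nx) - 0.5) / nx
  uy <- (seq_len(ny) - 0.5) / ny
  uz <- (seq_len(nz) - 0.5) / nz

  geo <- with_seed(spec@seed, {
    jit <- function(n = 3, a = 0.02) runif(n, -a, a)
    list(
      heart_ctr = c(0.42, 0.24, 0.45) + jit(),
      heart_rad = c(0.13, 0.11, 0.12) * runif(3, 0.92, 1.08),
      kid_l_ctr = c(0.32, 0.56, 0.60) + jit(),
      kid_r_ctr = c(0.68, 0.56, 0.60) + jit(),
      kid_rad   = c(0.07, 0.09, 0.06) * runif(3, 0.92, 1.08),
      blad_ctr  = c(0.50, 0.88, 0.50) + jit(3, 0.015),
      blad_rad  = c(0.08, 0.065, 0.08) * runif(3, 0.92, 1.08),
      int_mult  = runif(5, 0.85, 1.15)
    )
  })

  body <- .cylinder_y(ux, uy, uz, 0.5, 0.5, 0.42, 0.35)
  heart <- .ellipsoid(ux, uy, uz, geo$heart_ctr, geo$heart_rad)
  lv_out <- .ellipsoid(ux, uy, uz, geo$heart_ctr + c(0.015, 0.015, 0),
                       geo$heart_rad * 0.62)
  lv_in <- .ellipsoid(ux, uy, uz, geo$heart_ctr + c(0.015, 0.015, 0),
                      geo$heart_rad * 0.62 * 0.55)
  lv <- lv_out & !lv_in & heart
  kid <- .ellipsoid(ux, uy, uz, geo$kid_l_ctr, geo$kid_rad) |
    .ellipsoid(ux, uy, uz, geo$kid_r_ctr, geo$kid_rad)
  bladder <- .ellipsoid(ux, uy, uz, geo$blad_ctr, geo$blad_rad)

  # rib rings: band at the body surface in (x, z), periodic along y in the
  # thoracic segment; plus a posterior spinal column
  sxz <- outer((ux - 0.5)^2 / 0.40^2, (uz - 0.5)^2 / 0.33^2, "+")
  ring <- sxz >= 0.70 & sxz <= 1.05
  period <- max(4L, round(ny / 16))
  width <- max(2L, round(period * 0.4))
  stripe <- (seq_len(ny) %% period) < width
  thoracic <- uy >= 0.06 & uy <= 0.44
  ribs <- array(FALSE, gs)
  for (j in which(stripe & thoracic)) ribs[, j, ] <- ring
  spine <- .cylinder_y(ux, uy, uz, 0.5, 0.72, 0.065, 0.075, 0.04, 0.95)
  ribcage <- ribs | spine

  if (!any(lv) || !any(heart & !lv))
    stop("grid too small to place organs: LV shell unresolved at ",
         paste(gs, collapse = " x "))

  oi <- spec@organIntensities * c(
    soft_tissue = geo$int_mult[1], ribcage = geo$int_mult[2],
    kidneys = geo$int_mult[3], bladder = geo$int_mult[4],
    heart_blood = geo$int_mult[5])[names(spec@organIntensities)]

  act <- array(0, gs)
  act[body] <- oi["soft_tissue"]
  act[heart] <- oi["heart_blood"]
  act[kid] <- oi["kidneys"]
  act[bladder] <- oi["bladder"]
  act[ribcage] <- oi["ribcage"]

  f <- spec@cardiacUptakeFraction
  if (f > 0) {
    proj0 <- .sum_along(act, 3L)
    p99 <- pctl(proj0, 99)
    nvox <- .sum_along(lv + 0, 3L)
    support <- nvox > 0
    mean_thick <- mean(nvox[support])
    a <- f * p99 / mean_thick
    act <- act + a * lv
  }

  sp <- spec@spacingMm
  anatomy <- AnatomySet(list(
    lv = LabelMask(array(as.numeric(lv), gs), "lv", sp),
    whole_heart = LabelMask(array(as.numeric(heart | lv), gs),
                            "whole_heart", sp),
    ribcage = LabelMask(array(as.numeric(ribcage), gs), "ribcage", sp)))
  list(volume = ActivityVolume(act, sp, apAxis = 3L), anatomy = anatomy)
}

#' Add Poisson counting noise
#'
#' Rescales the input so its expected total equals `totalCounts` and draws
#' independent Poisson counts per voxel/pixel, emulating scintigraphy
#' counting statistics. Output values are nonnegative integers in the
#' original container type.
#'
#' @param x an [ActivityVolume-class] or [PlanarImage-class].
#' @param totalCounts expected total number of counts (>= 1).
#' @param seed integer RNG seed.
#' @return an object of the same class as `x` with Poisson-sampled values.
#' @examples
#' img <- PlanarImage(matrix(10, 32, 32))
#' noisy <- addCountingNoise(img, totalCounts = 1e5, seed = 1)
#' @export
setGeneric("addCountingNoise",
           function(x, totalCounts, seed) standardGeneric("addCountingNoise"))

.poisson_counts <- function(values, totalCounts, seed) {
  stopifnot(totalCounts >= 1)
  s <- sum(values)
  if (s <= 0) stop("cannot scale an all-zero input to a count total")
  lambda <- values * (totalCounts / s)
  with_seed(seed, {
    out <- rpois(length(lambda), lambda)
    array(as.numeric(out), dim(values) %||% length(values))
  })
}

#' @rdname addCountingNoise
setMethod("addCountingNoise", "ActivityVolume",
  function(x, totalCounts, seed) {
    ActivityVolume(.poisson_counts(x@voxels, totalCounts, seed),
                   x@spacingMm, x@apAxis)
  })

#' @rdname addCountingNoise
setMethod("addCountingNoise", "PlanarImage",
  function(x, totalCounts, seed) {
    px <- .poisson_counts(x@pixels, totalCounts, seed)
    PlanarImage(matrix(px, nrow(x@pixels)), x@spacingMm, x@view,
                x@patientId, x@acquisitionId)
  })

.DEFAULT_GRADE_INTERVALS <- list(`1` = c(0.10, 0.40), `2` = c(0.40, 0.90),
                                 `3` = c(0.90, 1.50))

#' Generate a labelled synthetic planar cohort
#'
#' Simulates `nPatients` patients: each gets a Perugini-style grade sampled
#' from `gradeProportions`, an LV uptake fraction drawn from the per-grade
#' interval, a jittered phantom, and anterior/posterior planar views obtained
#' by pseudo-planar projection with independent Poisson noise. The posterior
#' view is the left-right mirror of the anterior geometry with its own noise
#' realization. Ground-truth 2D masks (3D masks dilated by `dilateMm`, then
#' projected) are attached in the anterior frame.
#'
#' @param nPatients number of patients (>= 4).
#' @param gradeProportions length-4 probabilities for grades 0..3 (sum 1).
#' @param specTemplate [PhantomSpec-class] template (its uptake fraction and
#'   seed are overridden per patient).
#' @param seed cohort RNG seed.
#' @param totalCountsPerView expected Poisson counts per planar view; `NULL`
#'   or `Inf` disables noise.
#' @param gradeIntervals named list (`"1"`, `"2"`, `"3"`) of uptake-fraction
#'   intervals; grade 0 is always fraction 0.
#' @param dilateMm 3D mask dilation radius (mm) before projection.
#' @param keepMasks attach projected ground-truth masks to each case.
#' @return list of [LabeledCase-class].
#' @examples
#' \donttest{
#' cohort <- generateCohort(4, c(1, 0, 0, 0),
#'                          PhantomSpec(gridShape = 48), seed = 1)
#' }
#' @export
generateCohort <- function(nPatients, gradeProportions = rep(0.25, 4),
                           specTemplate = PhantomSpec(), seed = 1L,
                           totalCountsPerView = 2e6,
                           gradeIntervals = .DEFAULT_GRADE_INTERVALS,
                           dilateMm = 2, keepMasks = TRUE) {
  if (abs(sum(gradeProportions) - 1) > 1e-9)
    stop("gradeProportions must sum to 1 (tolerance 1e-9)")
  if (nPatients < 4) stop("nPatients must be >= 4")
  noisy <- !is.null(totalCountsPerView) && is.finite(totalCountsPerView)

  draws <- with_seed(seed, {
    list(grades = sample(0:3, nPatients, replace = TRUE,
                         prob = gradeProportions),
         u = runif(nPatients),
         subseeds = sample.int(.Machine$integer.max - 1L, 3L * nPatients))
  })

  cases <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    g <- draws$grades[i]
    f <- if (g == 0L) 0 else {
      iv <- gradeIntervals[[as.character(g)]]
      iv[1] + draws$u[i] * (iv[2] - iv[1])
    }
    spec_i <- PhantomSpec(gridShape = specTemplate@gridShape,
                          spacingMm = specTemplate@spacingMm,
                          organIntensities = specTemplate@organIntensities,
                          cardiacUptakeFraction = f,
                          seed = draws$subseeds[3 * i - 2])
    ph <- generatePhantom(spec_i)
    proj <- projectVolume(ph$volume)
    pid <- sprintf("P%03d", i)
    ant <- PlanarImage(pixels(proj), spacingMm(proj), "anterior", pid, "A1")
    post <- PlanarImage(mirror_lr(pixels(proj)), spacingMm(proj),
                        "posterior", pid, "A1")
    if (noisy) {
      ant <- addCountingNoise(ant, totalCountsPerView,
                              draws$subseeds[3 * i - 1])
      post <- addCountingNoise(post, totalCountsPerView,
                               draws$subseeds[3 * i])
      ant@view <- "anterior"; post@view <- "posterior"
      ant@patientId <- post@patientId <- pid
      ant@acquisitionId <- post@acquisitionId <- "A1"
    }
    masks <- list()
    if (keepMasks) {
      masks <- lapply(anatomyMasks(ph$anatomy), function(m) {
        projectMask(if (dilateMm > 0) dilateMask(m, dilateMm) else m)
      })
    }
    cases[[i]] <- LabeledCase(pid, "A1", g,
                              images = list(anterior = ant, posterior = post),
                              uptakeFraction = f, masks = masks)
  }
  cases
}
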