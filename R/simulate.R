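# Synthetic phantoms and rater-corruption models. The generator is the
# in-silico stand-in for expert-annotated CT ground truth: a tumor-like blob
# with controllable morphology, K raters whose masks corrupt the truth with
# known per-voxel sensitivity and specificity inside a dilated boundary band,
# and probability maps consistent with each rater's mask. Every random draw
# flows from an explicit seed.

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Generate a synthetic tumor phantom
#'
#' Deterministic (seeded) 3D label volume: an ellipsoid, optionally perturbed
#' radially to emulate lobulated (smooth, low-frequency) or spiky (sharp,
#' high-amplitude) tumor morphology, which controls the solidity regime of
#' the phantom. A voxel is tumor when its normalized ellipsoidal radius
#' `rho = sqrt(sum(((x - center) / radii)^2))` satisfies
#' `rho <= 1 + irregularity * f(direction)`, where `f` is a seeded smooth
#' angular field (lobulated: low-order azimuthal harmonics damped at the
#' poles; spiky: narrow Gaussian bumps around random directions), scaled to
#' `max |f| = 1`.
#'
#' @param grid a [VoxelGrid-class].
#' @param shapeKind `"ellipsoid"`, `"lobulated"` or `"spiky"`.
#' @param center phantom center in voxel coordinates (default grid center).
#' @param radii 3 positive semi-axes in voxels.
#' @param irregularity amplitude of the radial perturbation (>= 0; ignored
#'   for `"ellipsoid"`).
#' @param nLobes number of lobes / spikes.
#' @param seed integer seed; same spec and seed give a voxel-identical phantom.
#' @param organScale if non-`NULL`, an enclosing convex "organ" ellipsoid
#'   with semi-axes `radii * organScale` is added: labels become 0 =
#'   background, 1 = organ, 2 = tumor (tumor wins overlap). Otherwise labels
#'   are 0/1 with tumor = 1.
#' @return a [LabelVolume-class]; errors if the phantom could exceed the grid.
#' @export
makePhantom <- function(grid, shapeKind = c("ellipsoid", "lobulated", "spiky"),
                        center = NULL, radii = c(10, 10, 10),
                        irregularity = 0, nLobes = 5L, seed = 1L,
                        organScale = NULL) {
  shapeKind <- match.arg(shapeKind)
  stopifnot(is(grid, "VoxelGrid"), length(radii) == 3L, all(radii > 0),
            irregularity >= 0)
  if (is.null(center)) center <- (gridShape(grid) + 1) / 2
  if (shapeKind == "ellipsoid") irregularity <- 0

  reach <- radii * (1 + irregularity)
  if (!is.null(organScale)) reach <- pmax(reach, radii * organScale)
  if (any(center - reach < 1) || any(center + reach > gridShape(grid)))
    stop("phantom (radial reach ", paste(round(reach, 1), collapse = "x"),
         " voxels) exceeds the grid")

  d <- gridShape(grid)
  dx <- (seq_len(d[1]) - center[1]) / radii[1]
  dy <- (seq_len(d[2]) - center[2]) / radii[2]
  dz <- (seq_len(d[3]) - center[3]) / radii[3]
  DX <- array(dx, d)
  DY <- array(rep(dy, each = d[1]), d)
  DZ <- array(rep(dz, each = d[1] * d[2]), d)
  rho <- sqrt(DX^2 + DY^2 + DZ^2)

  limit <- 1
  if (irregularity > 0) {
    r0 <- pmax(rho, 1e-9)
    ux <- DX / r0; uy <- DY / r0; uz <- DZ / r0
    f <- .withSeed(seed, {
      if (shapeKind == "lobulated") {
        theta <- atan2(uy, ux)
        sin2 <- 1 - uz^2  # vanishes at the poles, keeps f continuous
        amp <- stats::runif(nLobes, -1, 1) / seq_len(nLobes)
        phase <- stats::runif(nLobes, 0, 2 * pi)
        g <- 0
        for (l in seq_len(nLobes)) g <- g + amp[l] * cos(l * theta + phase[l])
        g * sin2
      } else {  # spiky: narrow bumps around random directions
        nspike <- max(as.integer(nLobes), 6L)
        u <- matrix(stats::rnorm(3 * nspike), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        width <- 0.12
        g <- 0
        for (k in seq_len(nspike)) {
          ca <- pmin(pmax(ux * u[k, 1] + uy * u[k, 2] + uz * u[k, 3], -1), 1)
          g <- g + exp(-acos(ca)^2 / (2 * width^2))
        }
        g
      }
    })
    f <- f / max(abs(f))
    limit <- 1 + irregularity * f
  }
  tumor <- rho <= limit

  if (is.null(organScale)) {
    labels <- array(0L, d)
    labels[tumor] <- 1L
    return(new("LabelVolume", grid = grid, labels = labels, nClasses = 2L))
  }
  organ <- (DX / organScale)^2 + (DY / organScale)^2 + (DZ / organScale)^2 <= 1
  labels <- array(0L, d)
  labels[organ] <- 1L
  labels[tumor] <- 2L
  new("LabelVolume", grid = grid, labels = labels, nClasses = 3L)
}

#' Corrupt a truth mask into a simulated rater
#'
#' Generative inverse of the STAPLE observation model. Inside the truth,
#' each voxel is kept with probability `sensitivity`; inside the boundary
#' band (truth dilated by `roiMargin` face-connected steps, minus truth)
#' each voxel is switched on with probability `1 - specificity`; outside the
#' band everything stays background. Optionally, seeded morphological
#' boundary jitter then dilates or erodes random surface patches of radius
#' up to `boundaryNoiseRadius`, adding spatially correlated disagreement on
#' top of the i.i.d. flips. Deterministic given the seed.
#'
#' Specificity is defined within the band, not the whole volume: against a
#' full CT background every rater's whole-volume specificity is ~1 no matter
#' how sloppy its boundary is, so only a band-limited specificity is an
#' informative, recoverable parameter.
#'
#' @param truth a non-empty [BinaryMask-class].
#' @param sensitivity,specificity per-voxel Bernoulli rates in (0, 1].
#' @param roiMargin band width in voxels (face-connected dilation steps).
#' @param boundaryNoiseRadius max radius of jitter patches (0 = none).
#' @param nJitterPatches number of jitter patches when radius > 0.
#' @param seed integer seed.
#' @return a [BinaryMask-class] on the truth's grid.
#' @export
corruptRater <- function(truth, sensitivity, specificity, roiMargin = 3L,
                         boundaryNoiseRadius = 0L, nJitterPatches = 3L,
                         seed = 1L) {
  stopifnot(is(truth, "BinaryMask"),
            sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1)
  tv <- truth@values
  if (!any(tv)) stop("corruptRater: empty truth mask")
  band <- .dilate(tv, as.integer(roiMargin)) & !tv

  out <- .withSeed(seed, {
    o <- array(FALSE, dim(tv))
    o[tv] <- stats::runif(sum(tv)) < sensitivity
    o[band] <- stats::runif(sum(band)) < (1 - specificity)
    if (boundaryNoiseRadius > 0 && any(o)) {
      surf_idx <- which(.surface(o))
      if (length(surf_idx) > 0L) {
        centers <- sample(surf_idx, min(nJitterPatches, length(surf_idx)))
        for (ci in centers) {
          patch <- array(FALSE, dim(tv))
          patch[ci] <- TRUE
          patch <- .dilate(patch, as.integer(boundaryNoiseRadius))
          if (stats::runif(1) < 0.5) {
            o <- o | (patch & (tv | band))  # local dilation, kept inside the band
          } else {
            o <- o & !patch                 # local erosion
          }
        }
      }
    }
    o
  })
  new("BinaryMask", grid = truth@grid, values = out)
}

#' Synthesize a softmax-style probability map for a mask
#'
#' Emulates a model's per-class soft output consistent with its binary mask:
#' tumor probability is a logistic function of the signed Euclidean distance
#' (mm) to the mask boundary (positive inside), plus optional seeded Gaussian
#' perturbation, clamped and renormalized against the background class. With
#' no noise, thresholding the tumor class at 0.5 reproduces the mask for any
#' sharpness.
#'
#' @param mask a [BinaryMask-class].
#' @param sharpness logistic slope per mm (> 0); larger = crisper boundary.
#' @param noiseSD standard deviation of the additive Gaussian perturbation.
#' @param seed integer seed (used only when `noiseSD > 0`).
#' @return a two-class [ProbabilityField-class] (background, tumor).
#' @export
makeProbabilityMap <- function(mask, sharpness = 1.5, noiseSD = 0, seed = 1L) {
  stopifnot(is(mask, "BinaryMask"), sharpness > 0)
  fg <- mask@values
  d <- dim(fg)
  spacing <- gridSpacing(mask)
  eps <- 1e-6
  maxd <- 6 / sharpness  # logistic is saturated beyond this (mm)

  if (!any(fg) || all(fg)) {
    p <- array(if (any(fg)) 1 - eps else eps, d)
  } else {
    # signed distance: inside voxels to nearest background voxel, outside
    # voxels to nearest foreground voxel (both positive spacing away at the
    # boundary, so the 0.5 level sits between the two voxel layers); the
    # nearest opposite-phase voxel always lies in the 26-adjacent interface
    # layer, so those layers are the only distance candidates needed
    rB <- ceiling(maxd / min(spacing))
    sfg <- fg & !.erodeBox1(fg)            # fg voxels 26-adjacent to bg
    sbg <- .dilateBox1(fg) & !fg           # bg voxels 26-adjacent to fg
    near <- .dilate(.surface(fg), rB)
    sd_mm <- array(maxd, d)
    sd_mm[!fg] <- -maxd
    nin <- near & fg
    nout <- near & !fg
    if (any(nin))
      sd_mm[nin] <- pmin(.nearestDist(.coordsMM(nin, spacing),
                                      .coordsMM(sbg, spacing)), maxd)
    if (any(nout))
      sd_mm[nout] <- -pmin(.nearestDist(.coordsMM(nout, spacing),
                                        .coordsMM(sfg, spacing)), maxd)
    p <- stats::plogis(sharpness * sd_mm)
  }
  if (noiseSD > 0) {
    p <- p + .withSeed(seed, array(stats::rnorm(length(p), 0, noiseSD), d))
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  vals <- array(0, c(d, 2L))
  vals[, , , 1] <- 1 - p
  vals[, , , 2] <- p
  new("ProbabilityField", grid = mask@grid, values = vals)
}

#' Empirical rater performance against the generating truth
#'
#' Per-rater sensitivity and specificity measured directly against the truth
#' mask, with specificity evaluated inside the dilated boundary band (truth
#' dilated by `roiMargin`, minus truth) — the same band the corruption model
#' draws its false positives in. This is the oracle STAPLE's parameter
#' estimates are compared against.
#'
#' @param raters a [RaterSet-class].
#' @param truth the generating [BinaryMask-class].
#' @param roiMargin band width in voxels.
#' @return `data.frame` with columns `rater, emp_sens, emp_spec`.
#' @export
empiricalRaterPerformance <- function(raters, truth, roiMargin = 3L) {
  stopifnot(is(raters, "RaterSet"), is(truth, "BinaryMask"))
  checkSameGrid(raters, truth)
  tv <- truth@values
  band <- .dilate(tv, as.integer(roiMargin)) & !tv
  rows <- lapply(seq_len(nRaters(raters)), function(j) {
    m <- raters@masks[[j]]@values
    data.frame(rater = raters@raterNames[j],
               emp_sens = sum(m & tv) / sum(tv),
               emp_spec = sum(!m & band) / sum(band),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration of a synthetic ensemble experiment
#'
#' Bundles the study conditions of the simulated multi-rater regime. The
#' defaults define the heterogeneous-reliability regime used throughout the
#' package's validation: 64^3 voxels at 1 mm isotropic spacing, lobulated
#' phantoms with semi-axes drawn uniformly from 8-14 voxels, five raters
#' with sensitivities spanning 0.95 down to 0.60 at band specificity 0.995,
#' and probability maps with logistic sharpness 1.5/mm and noise SD 0.05.
#' The full configuration plus the master seed determines every output
#' bit-exactly; per-case and per-rater child seeds are derived by fixed
#' arithmetic, so adding cases never reshuffles existing ones.
#'
#' @param nCases number of simulated cases.
#' @param gridShape,spacing grid geometry.
#' @param shapeKind,irregularity,nLobes,radiiRange phantom morphology; radii
#'   are drawn per case uniformly from `radiiRange` (voxels).
#' @param sensitivities per-rater true sensitivities (length K).
#' @param specificity band specificity shared by all raters.
#' @param roiMargin boundary band width in voxels.
#' @param boundaryNoiseRadius jitter radius passed to [corruptRater()].
#' @param sharpness,noiseSD probability-map parameters.
#' @param stapleParams [StapleParams-class] used for the STAPLE fusion.
#' @param threshold STAPLE weight threshold for the final mask.
#' @param seed master seed.
#' @return an `ExperimentConfig` list (classed).
#' @export
experimentConfig <- function(nCases = 30L,
                             gridShape = c(64L, 64L, 64L),
                             spacing = c(1, 1, 1),
                             shapeKind = "lobulated",
                             irregularity = 0.15,
                             nLobes = 5L,
                             radiiRange = c(8, 14),
                             sensitivities = c(0.95, 0.90, 0.85, 0.70, 0.60),
                             specificity = 0.995,
                             roiMargin = 3L,
                             boundaryNoiseRadius = 0L,
                             sharpness = 1.5,
                             noiseSD = 0.05,
                             stapleParams = StapleParams(),
                             threshold = 0.5,
                             seed = 1L) {
  cfg <- list(nCases = as.integer(nCases), gridShape = as.integer(gridShape),
              spacing = as.numeric(spacing), shapeKind = shapeKind,
              irregularity = irregularity, nLobes = as.integer(nLobes),
              radiiRange = as.numeric(radiiRange),
              sensitivities = as.numeric(sensitivities),
              specificity = specificity, roiMargin = as.integer(roiMargin),
              boundaryNoiseRadius = as.integer(boundaryNoiseRadius),
              sharpness = sharpness, noiseSD = noiseSD,
              stapleParams = stapleParams, threshold = threshold,
              seed = as.integer(seed))
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Simulate one case of an experiment
#'
#' Generates the truth phantom, the K corrupted rater masks and their
#' probability maps for case `caseIndex` of a configuration. Exposed so
#' tests and scripts can reuse single cases; [runEnsembleExperiment()] calls
#' it per case.
#'
#' @param cfg an [experimentConfig()] object.
#' @param caseIndex 1-based case number.
#' @param withMaps generate probability maps? Set `FALSE` when only masks
#'   are needed (e.g. parameter-recovery runs); truth and rater draws are
#'   unaffected.
#' @return list with `truth` ([BinaryMask-class]), `raters`
#'   ([RaterSet-class]) and `maps` (list of [ProbabilityField-class], or
#'   `NULL` when `withMaps = FALSE`).
#' @export
simulateCase <- function(cfg, caseIndex, withMaps = TRUE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  grid <- VoxelGrid(cfg$gridShape, cfg$spacing)
  phantom_seed <- .childSeed(cfg$seed, caseIndex, 0L)
  radii <- .withSeed(phantom_seed,
                     stats::runif(3, cfg$radiiRange[1], cfg$radiiRange[2]))
  vol <- makePhantom(grid, shapeKind = cfg$shapeKind, radii = radii,
                     irregularity = cfg$irregularity, nLobes = cfg$nLobes,
                     seed = phantom_seed)
  truth <- extractClassMask(vol, 1L)
  K <- length(cfg$sensitivities)
  masks <- lapply(seq_len(K), function(j) {
    corruptRater(truth, cfg$sensitivities[j], cfg$specificity,
                 roiMargin = cfg$roiMargin,
                 boundaryNoiseRadius = cfg$boundaryNoiseRadius,
                 seed = .childSeed(cfg$seed, caseIndex, j))
  })
  raters <- RaterSet(masks, paste0("M", seq_len(K)))
  maps <- NULL
  if (withMaps) {
    maps <- lapply(seq_len(K), function(j) {
      makeProbabilityMap(masks[[j]], sharpness = cfg$sharpness,
                         noiseSD = cfg$noiseSD,
                         seed = .childSeed(cfg$seed, caseIndex, 100L + j))
    })
  }
  list(truth = truth, raters = raters, maps = maps)
}

#' Run a full synthetic ensemble experiment
#'
#' The in-silico analogue of the fuse-evaluate-compare workflow: for each
#' case, generate the truth and K rater masks plus probability maps, fuse
#' with majority voting, soft voting (average of the maps, then argmax) and
#' STAPLE (EM weights thresholded at the configured value), evaluate every
#' individual rater and fusion method against the truth, and run the paired
#' comparison protocol. Fully reproducible from the configuration.
#'
#' @param cfg an [experimentConfig()] object.
#' @return list with
#'   \describe{
#'     \item{summary}{per-method, per-metric `mean`, `sd`, `n` table}
#'     \item{reports}{named list of per-method [metricReport()] tables}
#'     \item{comparison}{the [compareMethods()] table}
#'     \item{estimates}{per case and rater: STAPLE-estimated vs empirical
#'       sensitivity/specificity (empirical measured in the truth band)}
#'     \item{config}{the configuration}
#'   }
#' @export
runEnsembleExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  K <- length(cfg$sensitivities)
  method_names <- c(paste0("M", seq_len(K)), "majority", "soft", "staple")
  reports <- stats::setNames(vector("list", length(method_names)), method_names)
  estimates <- NULL

  for (i in seq_len(cfg$nCases)) {
    case <- simulateCase(cfg, i)
    case_id <- sprintf("case%03d", i)
    sres <- stapleEM(case$raters, cfg$stapleParams)
    preds <- c(
      stats::setNames(case$raters@masks, paste0("M", seq_len(K))),
      list(majority = majorityVote(case$raters),
           soft = extractClassMask(argmaxLabels(softVote(case$maps)), 1L),
           staple = thresholdWeights(sres, cfg$threshold)))
    for (nm in method_names) {
      reports[[nm]] <- rbind(reports[[nm]],
                             metricReport(preds[[nm]], case$truth, caseId = case_id))
    }
    emp <- empiricalRaterPerformance(case$raters, case$truth, cfg$roiMargin)
    estimates <- rbind(estimates, data.frame(
      case_id = case_id, rater = emp$rater,
      est_sens = unname(sensitivities(sres)),
      est_spec = unname(specificities(sres)),
      emp_sens = emp$emp_sens, emp_spec = emp$emp_spec,
      stringsAsFactors = FALSE))
  }

  metrics <- c("dsc", "ji", "hd95_mm", "precision", "recall")
  summary <- do.call(rbind, lapply(method_names, function(nm) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- reports[[nm]][[m]]
      v <- v[is.finite(v)]
      data.frame(method = nm, metric = m, mean = mean(v), sd = stats::sd(v),
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))

  comparison <- compareMethods(reports, staple = "staple", soft = "soft",
                               exclude = "majority", metrics = metrics)
  list(summary = summary, reports = reports, comparison = comparison,
       estimates = estimates, config = cfg)
}
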