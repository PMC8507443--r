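#' Construct a phantom specification
#'
#' Creates a validated [PhantomSpec-class].  Defaults describe a
#' 96 mm isotropic field of view at 1 mm voxels with representative CT
#' tissue intensities (soft tissue 0 HU, muscle 50 HU, cortical bone
#' 1200 HU, marrow 150 HU, patient table -300 HU), a 2 mm femoral-shaft
#' cortex, a 0.8 mm partial-volume blur and 15 HU additive noise.
#'
#' @param shape integer(3) voxels, each >= 32.
#' @param spacing numeric(3), mm.
#' @param bodyHU,muscleHU,corticalHU,marrowHU,tableHU tissue HU values.
#' @param corticalThicknessMM shaft cortex thickness, mm; the thin-cortex
#'   regions (femoral head, pelvic ring, acetabulum) use half this value.
#' @param nForamina total number of cortical perforations, alternating
#'   between the two femoral shafts.
#' @param foramenRadiusMM perforation radius, mm.
#' @param jointGapMM hip-joint space width, mm.
#' @param osteoporosisFactor multiplier in (0, 1] applied to the
#'   cortical intensity; factors below 1 additionally carve smooth
#'   low-density patches into the thin-cortex sites (regional mineral
#'   loss) and scale the marrow contrast over soft tissue (trabecular
#'   rarefaction).
#' @param blurSigmaMM Gaussian blur sigma, mm.
#' @param noiseSDHU additive Gaussian noise SD, HU.
#' @param includeTable add a detached patient-table slab.
#' @param shaftOpen turn the femoral shafts into open-ended axial tubes
#'   (canal fixture); omits heads, acetabula and pelvic ring.
#' @param seed RNG seed for the noise.
#' @return a [PhantomSpec-class].
#' @examples
#' phantomSpec(shape = c(64, 64, 64), seed = 7)
#' @export
phantomSpec <- function(shape = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                        bodyHU = 0, muscleHU = 50, corticalHU = 1200,
                        marrowHU = 150, tableHU = -300,
                        corticalThicknessMM = 2, nForamina = 4L,
                        foramenRadiusMM = 1.5, jointGapMM = 8,
                        osteoporosisFactor = 1, blurSigmaMM = 0.8,
                        noiseSDHU = 15, includeTable = TRUE,
                        shaftOpen = FALSE, seed = 1L) {
    new("PhantomSpec", shape = as.integer(shape),
        spacing = as.numeric(spacing), bodyHU = as.numeric(bodyHU),
        muscleHU = as.numeric(muscleHU),
        corticalHU = as.numeric(corticalHU),
        marrowHU = as.numeric(marrowHU), tableHU = as.numeric(tableHU),
        corticalThicknessMM = as.numeric(corticalThicknessMM),
        nForamina = as.integer(nForamina),
        foramenRadiusMM = as.numeric(foramenRadiusMM),
        jointGapMM = as.numeric(jointGapMM),
        osteoporosisFactor = as.numeric(osteoporosisFactor),
        blurSigmaMM = as.numeric(blurSigmaMM),
        noiseSDHU = as.numeric(noiseSDHU),
        includeTable = isTRUE(includeTable),
        shaftOpen = isTRUE(shaftOpen), seed = as.integer(seed))
}

#' Named preset phantom specifications
#'
#' Ready-made [PhantomSpec-class] configurations covering the main
#' study conditions: `"default"`; `"osteoporosis"` (factor 0.5, the
#' low-contrast thin-cortex case); `"kissing_joint"` (4 mm joint space,
#' the femoral-head/acetabulum bridging fixture); `"perforated"`
#' (8 cortical foramina); `"canal"` (axially open tubes, the 2D-vs-3D
#' hole-filling contrast fixture).
#'
#' @param shape,seed passed through to every preset.
#' @return a named list of [PhantomSpec-class] objects.
#' @examples
#' names(presetSpecs())
#' presetSpecs()$kissing_joint@jointGapMM
#' @export
presetSpecs <- function(shape = c(96L, 96L, 96L), seed = 1L) {
    list(
        default = phantomSpec(shape = shape, seed = seed),
        osteoporosis = phantomSpec(shape = shape, seed = seed,
            osteoporosisFactor = 0.5),
        kissing_joint = phantomSpec(shape = shape, seed = seed,
            jointGapMM = 4),
        perforated = phantomSpec(shape = shape, seed = seed,
            nForamina = 8L),
        canal = phantomSpec(shape = shape, seed = seed,
            shaftOpen = TRUE, nForamina = 0L))
}

# Layout constants in mm at the reference field of view (96 mm); all
# are multiplied by min(extent)/96 so the anatomy scales with the grid.
.LAYOUT <- list(
    bodyA = 46, bodyB = 36,          # body ellipse semi-axes (x, y)
    muscleA = 40, muscleB = 30,
    shaftR = 14, shaftBottom = -46,  # femoral shaft outer radius
    headR = 15,                      # femoral head radius
    torusZ = 25, torusR = 8, torusTubeR = 7,
    jointDir = c(0.5, 0, -sqrt(3) / 2),  # torus -> head direction
    cupHalfAngleDeg = 25,
    fossaDepthMM = 6,  # acetabular fossa: cup deepens toward its axis
    canalX = 25,
    tableGapMM = 5, tableThicknessMM = 5, tableX = 36,
    foramenDepthFrac = 0.5)          # foramen centre depth into cortex

#' Generate a synthetic pelvic CT phantom with ground truth
#'
#' Builds a body-shaped soft-tissue background with an inner muscle
#' region, two femoral structures (spherical head on a capped
#' cylindrical shaft, thick shaft cortex and thin head cortex enclosing
#' marrow), a pelvic ring (torus, thin cortex) with an acetabular cup
#' facing each femoral head across `jointGapMM` of soft tissue,
#' `nForamina` cortical perforations, and optionally a detached
#' patient-table slab.  The volume is then degraded by a Gaussian blur
#' (partial-volume effect) and additive Gaussian noise (seeded).  The
#' ground-truth [LabelVolume-class] (1 = cortical bone, 2 = marrow
#' interior) is computed from the pre-blur geometry, so evaluation
#' against it measures the segmentation algorithm, not the corruption.
#'
#' The anatomy scales with the physical field of view; cortical
#' thickness, foramen radius, joint gap, blur and noise stay in
#' absolute mm/HU.  `osteoporosisFactor` scales the cortical intensity
#' globally and, below 1, additionally imposes a smooth deterministic
#' pattern of regional density loss on the thin-cortex sites (femoral
#' heads, pelvic ring, acetabula), whose low-density patches deepen and
#' widen as the factor decreases, and scales the marrow-over-soft-tissue
#' contrast (trabecular rarefaction).  A global intensity scaling alone
#' is largely undone by histogram matching; the regional structural
#' loss and the collapse of the marrow/soft-tissue contrast are what
#' make osteoporotic bone genuinely harder to segment.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements `volume` (a [CTVolume-class]), `truth`
#'   (a [LabelVolume-class]) and `spec`.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 48)))
#' table(voxelData(ph$truth))
#' @export
generatePhantom <- function(spec = phantomSpec()) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    L <- .LAYOUT
    d <- spec@shape
    sp <- spec@spacing
    extent <- d * sp
    s <- min(extent) / 96
    f <- spec@osteoporosisFactor
    tShaft <- spec@corticalThicknessMM
    tThin <- 0.5 * spec@corticalThicknessMM
    corticalVal <- spec@corticalHU * f
    # trabecular rarefaction: marrow attenuation falls toward soft
    # tissue as mineral is lost
    marrowVal <- spec@bodyHU + (spec@marrowHU - spec@bodyHU) * f

    # voxel-centre coordinates, volume centred on the origin
    cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
    cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
    cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
    X <- array(cx, d)
    Y <- array(rep(cy, each = d[1]), d)
    Z <- array(rep(cz, each = d[1] * d[2]), d)

    bodyA <- L$bodyA * s; bodyB <- L$bodyB * s
    body <- (X / bodyA)^2 + (Y / bodyB)^2 <= 1
    muscle <- (X / (L$muscleA * s))^2 + (Y / (L$muscleB * s))^2 <= 1

    shaftR <- L$shaftR * s
    headR <- L$headR * s
    torusZ <- L$torusZ * s
    torusR <- L$torusR * s
    torusTubeR <- L$torusTubeR * s
    zBottom <- L$shaftBottom * s
    u <- L$jointDir
    jointDist <- torusTubeR + spec@jointGapMM + headR

    marrow <- array(FALSE, d)
    cortical <- array(FALSE, d)      # thick (diaphyseal) cortex
    corticalThin <- array(FALSE, d)  # thin-cortex sites (head/ring/cup)
    headCentres <- list()

    if (spec@shaftOpen) {
        for (side in c(-1, 1)) {
            x0 <- side * L$canalX * s
            r2 <- (X - x0)^2 + Y^2
            solid <- r2 <= shaftR^2
            lumen <- r2 <= (shaftR - tShaft)^2
            cortical <- cortical | (solid & !lumen)
            # open canal: the lumen is soft tissue, not marrow
        }
    } else {
        tube <- c(torusR, 0, torusZ)   # a point on the torus centreline
        for (side in c(-1, 1)) {
            hc <- c(side * (tube[1] + abs(u[1]) * jointDist),
                tube[2],
                tube[3] + u[3] * jointDist)
            headCentres[[length(headCentres) + 1L]] <- hc
            if (hc[1] * side + headR > bodyA - s ||
                abs(hc[3]) + headR > max(abs(cz)))
                stop("phantom spec error: femoral structures exceed ",
                    "the body outline (joint gap too large for this ",
                    "field of view)", call. = FALSE)
            r2 <- (X - hc[1])^2 + Y^2
            shaftSolid <- r2 <= shaftR^2 & Z >= zBottom & Z <= hc[3]
            shaftInner <- r2 <= (shaftR - tShaft)^2 &
                Z >= zBottom + tShaft & Z <= hc[3]
            hd2 <- (X - hc[1])^2 + Y^2 + (Z - hc[3])^2
            headSolid <- hd2 <= headR^2
            headInner <- hd2 <= (headR - tThin)^2
            solid <- shaftSolid | headSolid
            inner <- shaftInner | headInner
            cortical <- cortical | (shaftSolid & !inner)
            corticalThin <- corticalThin | (headSolid & !inner)
            marrow <- marrow | inner
        }
        # pelvic ring: torus in the axial plane, thin cortex
        td <- sqrt((sqrt(X^2 + Y^2) - torusR)^2 + (Z - torusZ)^2)
        corticalThin <- corticalThin |
            (td <= torusTubeR & td > torusTubeR - tThin)
        marrow <- marrow | (td <= torusTubeR - tThin)
        # acetabular cups: spherical caps facing each femoral head.
        # The articular surface deepens toward its axis (acetabular
        # fossa): the joint space is jointGapMM wide at the rim and
        # fossaDepthMM wider centrally.  The fossa is carved out of the
        # pelvic bone and floored with thin cortex -- the configuration
        # in which part merging can seal the narrow rim while the deep
        # central space stays open, so hole filling then labels the
        # enclosed joint space as marrow (the bridging failure mode).
        cosCap <- cos(L$cupHalfAngleDeg * pi / 180)
        for (k in seq_along(headCentres)) {
            hc <- headCentres[[k]]
            side <- sign(hc[1])
            dirx <- -side * u[1]; dirz <- -u[3]
            dx <- X - hc[1]; dy <- Y; dz <- Z - hc[3]
            dist <- sqrt(dx^2 + dy^2 + dz^2)
            cosang <- (dx * dirx + dz * dirz) / pmax(dist, 1e-9)
            cone <- cosang >= cosCap
            h <- pmin(pmax((cosang - cosCap) / (1 - cosCap), 0), 1)^2
            rIn <- headR + spec@jointGapMM + L$fossaDepthMM * h
            carve <- cone & dist < rIn & dist >= headR
            cortical <- cortical & !carve
            corticalThin <- corticalThin & !carve
            marrow <- marrow & !carve
            floor <- cone & dist >= rIn & dist <= rIn + tThin
            corticalThin <- corticalThin | floor
        }
    }
    corticalThin <- corticalThin & !cortical
    marrow <- marrow & !(cortical | corticalThin)

    # cortical perforations (foramina) on the shafts
    if (spec@nForamina > 0L) {
        golden <- pi * (3 - sqrt(5))
        zTop <- if (spec@shaftOpen) max(cz) else
            min(vapply(headCentres, `[`, numeric(1), 3L)) - headR / 2
        for (k in seq_len(spec@nForamina)) {
            side <- if (k %% 2L == 1L) -1 else 1
            x0 <- if (spec@shaftOpen) side * L$canalX * s else
                headCentres[[if (k %% 2L == 1L) 1L else 2L]][1]
            th <- golden * k
            fr <- (k - 0.5) / spec@nForamina
            zk <- zBottom + (0.15 + 0.7 * fr) * (zTop - zBottom)
            rc <- shaftR - L$foramenDepthFrac * tShaft
            centre <- c(x0 + rc * cos(th), rc * sin(th), zk)
            fd2 <- (X - centre[1])^2 + (Y - centre[2])^2 +
                (Z - centre[3])^2
            hole <- fd2 <= spec@foramenRadiusMM^2
            cortical <- cortical & !hole
            corticalThin <- corticalThin & !hole
        }
    }

    vals <- array(-1000, d)
    vals[body] <- spec@bodyHU
    vals[body & muscle] <- spec@muscleHU
    vals[marrow] <- marrowVal
    vals[cortical] <- corticalVal
    vals[corticalThin] <- corticalVal
    if (f < 1 && any(corticalThin)) {
        # regional mineral-density loss at the thin-cortex sites:
        # a smooth, deterministic spatial pattern w in [0, 1] modulates
        # the local density as f^(4 w), so low-density patches deepen
        # and widen (as nested sets) as the factor decreases.  Unlike a
        # global intensity scaling, this structural change cannot be
        # undone by histogram matching: patch intensities sink into the
        # marrow/soft-tissue value range.
        wavelength <- 34 * s
        k <- c(0.55, 0.62, 0.56) / sqrt(sum(c(0.55, 0.62, 0.56)^2))
        idx <- which(corticalThin)
        phase <- 2 * pi * (X[idx] * k[1] + Y[idx] * k[2] +
            Z[idx] * k[3]) / wavelength
        w <- 0.5 * (1 + sin(phase))
        vals[idx] <- corticalVal * f^(4 * w)
    }
    if (spec@includeTable) {
        # the gap to the body stays in absolute mm so the table is
        # never within reach of the skin-closing step of table removal
        ty0 <- L$bodyB * s + L$tableGapMM
        ty1 <- min(ty0 + L$tableThicknessMM, max(cy))
        if (ty1 > ty0) {
            tbl <- Y >= ty0 & Y <= ty1 & abs(X) <= L$tableX * s
            vals[tbl] <- spec@tableHU
        }
    }

    truth <- array(0L, d)
    truth[cortical | corticalThin] <- 1L
    truth[marrow] <- 2L

    vals <- .gaussianBlur(vals, spec@blurSigmaMM, sp)
    if (spec@noiseSDHU > 0) {
        hasSeed <- exists(".Random.seed", envir = globalenv(),
            inherits = FALSE)
        if (hasSeed)
            oldSeed <- get(".Random.seed", envir = globalenv())
        set.seed(spec@seed)
        vals <- vals + stats::rnorm(length(vals), sd = spec@noiseSDHU)
        if (hasSeed)
            assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }
    vals <- pmin(pmax(vals, -1024), 3071)

    list(volume = CTVolume(vals, spacing = sp,
            origin = -((d - 1) / 2) * sp),
        truth = LabelVolume(truth, spacing = sp,
            origin = -((d - 1) / 2) * sp),
        spec = spec)
}
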