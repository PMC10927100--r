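#' Configuration for the synthetic dataset generator
#'
#' Collects every tunable of [simulate_dataset()] with validation. The
#' defaults emulate the structure of the study system: 16 regions, 86 NACs
#' (two of them unassigned), seven macro-units with Table-3-like relative
#' sizes, 24 toolkit and 52 technology traits, tri-state trait noise, and
#' armature outline families whose within-group dispersion can increase
#' across time-slices.
#'
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @param n_regions number of regions (default 16).
#' @param n_nacs number of NACs (default 86, of which `n_unassigned` stay
#'   outside the macro-units).
#' @param n_macro_units number of planted macro-units (default 7, max 7).
#' @param trait_counts named integer vector `c(tools =, technology =)`.
#' @param p_in archetype strength in (0.5, 1]: probability that a unit's
#'   archetype state is unit-specific rather than inherited from the global
#'   base vector. Larger values separate units more.
#' @param noise_flip_rate per-cell probability of flipping the archetype
#'   state, in \[0, 0.5).
#' @param missing_rate per-cell probability of replacing the state with
#'   unknown, in \[0, 1).
#' @param outlines_per_nac target outlines per NAC; each macro-unit
#'   contributes `outlines_per_nac * round(unit size / 4)` outlines to every
#'   time-slice (round-robin over its NACs present in that slice), so the
#'   family composition of every slice is identical by construction and
#'   per-slice disparity reflects the dispersion schedule, not sampling
#'   composition. Unassigned NACs get no outlines (generic taxa without
#'   published images).
#' @param shape_dispersion_by_slice named positive numeric vector
#'   `c(I=,II=,III=,IV=)`: coefficient-noise scale per slice.
#' @param family_blend in (0, 1]: optional extra shrinkage of each family
#'   template toward the mean template (1 = templates as authored). The
#'   authored silhouettes are already close variants of a common pointed
#'   form, so the default applies no extra shrinkage.
#' @param shape_drift_per_slice magnitude of the deterministic per-slice
#'   drift of each family's mean shape (plants a chronological signal).
#' @param spatial_decay_km length scale separating region centroids; site
#'   scatter within a region is ~ this / 6.
#' @param time_slice_weights sampling weights for the single time-slice of
#'   each NAC.
#' @param n_multi_slice number of NACs spanning two adjacent slices
#'   (default 2, so 86 NACs expand to 88 observations).
#' @param n_unassigned NACs left outside all macro-units (default 2).
#' @param sites_per_nac sites generated per NAC (default 2).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_regions = 16L,
                             n_nacs = 86L,
                             n_macro_units = 7L,
                             trait_counts = c(tools = 24L, technology = 52L),
                             p_in = 0.9,
                             noise_flip_rate = 0.05,
                             missing_rate = 0.1,
                             outlines_per_nac = 6L,
                             shape_dispersion_by_slice =
                               c(I = 0.05, II = 0.05, III = 0.10, IV = 0.14),
                             family_blend = 1,
                             shape_drift_per_slice = 0.06,
                             spatial_decay_km = 300,
                             time_slice_weights =
                               c(I = 0.2, II = 0.3, III = 0.25, IV = 0.25),
                             n_multi_slice = 2L,
                             n_unassigned = 2L,
                             sites_per_nac = 2L) {
  if (p_in <= 0.5 || p_in > 1) stop("p_in must lie in (0.5, 1]", call. = FALSE)
  if (noise_flip_rate < 0 || noise_flip_rate >= 0.5) {
    stop("noise_flip_rate must lie in [0, 0.5)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n_macro_units > 7L) stop("at most 7 macro-units", call. = FALSE)
  if (n_nacs < n_macro_units) {
    stop("n_nacs must be >= n_macro_units", call. = FALSE)
  }
  if (any(shape_dispersion_by_slice <= 0)) {
    stop("shape dispersions must be positive", call. = FALSE)
  }
  if (family_blend <= 0 || family_blend > 1) {
    stop("family_blend must lie in (0, 1]", call. = FALSE)
  }
  if (!identical(sort(names(shape_dispersion_by_slice)),
                 sort(time_slice_levels()))) {
    stop("shape_dispersion_by_slice needs names I..IV", call. = FALSE)
  }
  if (length(time_slice_weights) != 4L || any(time_slice_weights < 0) ||
      sum(time_slice_weights) <= 0) {
    stop("invalid time_slice_weights", call. = FALSE)
  }
  if (n_unassigned + n_macro_units * 2L > n_nacs) {
    stop("too few NACs for the requested unit structure", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 n_nacs = as.integer(n_nacs),
                 n_macro_units = as.integer(n_macro_units),
                 trait_counts = trait_counts, p_in = p_in,
                 noise_flip_rate = noise_flip_rate,
                 missing_rate = missing_rate,
                 outlines_per_nac = as.integer(outlines_per_nac),
                 shape_dispersion_by_slice =
                   shape_dispersion_by_slice[time_slice_levels()],
                 family_blend = family_blend,
                 shape_drift_per_slice = shape_drift_per_slice,
                 spatial_decay_km = spatial_decay_km,
                 time_slice_weights = time_slice_weights,
                 n_multi_slice = as.integer(n_multi_slice),
                 n_unassigned = as.integer(n_unassigned),
                 sites_per_nac = as.integer(sites_per_nac)),
            class = "generator_config")
}

# densify a polygon by linear interpolation along its edges
.densify_polygon <- function(poly, per_edge = 8L) {
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    t <- (seq_len(per_edge) - 1) / per_edge
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2])))
  }
  out
}

.polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# hand-authored armature silhouettes, one per family: six variants of a
# common elongated pointed form (as real armature classes are), each with a
# slowly tapering blunt base and a sharply tapering distal tip. The tip/base
# asymmetry keeps the starting vertex stable under digitization-style
# noise (a symmetric piece would split into two start-point modes); the
# mutual similarity of the variants keeps between-family shape separation
# comparable to within-family dispersion, so per-slice disparity responds
# to the dispersion schedule rather than being fixed by family identity.
.family_polygons <- function() {
  variant <- function(L, W, blunt, sharp, bend, lower = 0.9, n = 40L) {
    t <- seq(0, 1, length.out = n)
    prof <- t^blunt * (1 - t)^sharp
    w <- W * prof / max(prof)
    x <- L * (1 - t)                      # tip at x = 0, base at x = L
    mid <- bend * sin(pi * t)             # arched back when bend > 0
    rbind(cbind(x, mid + w)[-n, ], cbind(rev(x), rev(mid - lower * w))[-n, ])
  }
  list(
    tanged_point     = variant(2.10, 0.33, 0.40, 1.90, 0.00),
    arch_backed      = variant(1.90, 0.30, 0.50, 1.70, 0.04, lower = 0.85),
    trapeze          = variant(1.80, 0.36, 0.55, 1.60, 0.00, lower = 1.00),
    triangle         = variant(2.00, 0.38, 0.45, 1.80, 0.00, lower = 0.80),
    shouldered_point = variant(2.00, 0.37, 0.45, 1.50, -0.04),
    simple_point     = variant(2.00, 0.35, 0.50, 1.60, 0.00)
  )
}

#' Armature shape families
#'
#' Six hand-authored armature silhouettes (tanged point, arch-backed piece,
#' trapeze, triangle, shouldered point, simple point), each reduced to an
#' elliptic Fourier template after standard preprocessing, with
#' per-coefficient dispersion multipliers that decay with harmonic order so
#' that sampled perturbations stay smooth and closed.
#'
#' @param n_harmonics harmonics per template (default 10).
#' @return Named list of `shape_family` objects: `family_name`, `template`
#'   (`efa_coefficients`), `dispersion` (matrix of sd multipliers).
#' @export
shape_families <- function(n_harmonics = 10L) {
  polys <- .family_polygons()
  lapply(stats::setNames(names(polys), names(polys)), function(nm) {
    o <- preprocess_outline(outline(polys[[nm]], nm),
                            smooth_iterations = 2L, k = 200L)
    template <- efa_forward(o, n_harmonics)
    # noise multipliers: damped on the first harmonic (within-class
    # variation is mostly in proportions, not gross ellipse), 1/h beyond
    disp <- matrix(rep(1 / seq_len(n_harmonics), 4L), ncol = 4L)
    disp[1, ] <- 0.25
    structure(list(family_name = nm, template = template, dispersion = disp),
              class = "shape_family")
  })
}

#' Sample one outline from a shape family
#'
#' Perturbs the family's template coefficients with independent zero-mean
#' Gaussian noise of sd `sigma * dispersion` and reconstructs the curve by
#' inverse elliptic Fourier evaluation at `k_points` (>= 128) positions.
#' Degenerate draws (near-zero enclosed area) are resampled up to
#' `max_retry` times.
#'
#' @param family a `shape_family` from [shape_families()].
#' @param sigma positive noise scale.
#' @param seed optional integer seed.
#' @param k_points reconstruction resolution (default 128).
#' @param drift optional numeric matrix added to the template coefficients
#'   before noise (systematic shape shift).
#' @param artefact_id id for the generated outline.
#' @param max_retry resample cap (default 10).
#' @return An [outline()].
#' @export
simulate_outline <- function(family, sigma, seed = NULL, k_points = 128L,
                             drift = NULL, artefact_id = "synthetic",
                             max_retry = 10L) {
  stopifnot(inherits(family, "shape_family"))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  co <- family$template
  if (!is.null(drift)) co$coef <- co$coef + drift
  draw <- function() {
    for (i in seq_len(max_retry)) {
      pert <- co
      pert$coef <- co$coef +
        matrix(stats::rnorm(length(co$coef), 0, sigma), nrow(co$coef)) *
        family$dispersion
      out <- efa_inverse(pert, k_points, artefact_id = artefact_id)
      if (.polygon_area(out$coords) > 1e-4) return(out)
    }
    stop("degenerate outline after ", max_retry, " retries", call. = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# fixed drift direction shared by all families: harmonics >= 2 only (so
# size normalization cannot wash it out), alternating signs, 1/h decay.
# A common mean shift moves every slice's cloud as a block: it plants a
# chronological signal in between-slice distances while leaving each
# slice's internal variance (hence disparity) untouched.
.slice_drift <- function(n_harm) {
  d <- matrix(rep(1 / seq_len(n_harm), 4L), ncol = 4L)
  sgn <- matrix(ifelse(outer(seq_len(n_harm), 1:4, "+") %% 2L == 0L, 1, -1),
                n_harm)
  d[1, ] <- 0
  d * sgn
}

# near-proportional largest-remainder allocation of k NACs to time-slices,
# shuffled; keeps every unit's family represented in every slice so that
# per-slice disparity is not confounded by family-mix composition
.alloc_slices <- function(k, weights) {
  raw <- weights / sum(weights) * k
  cnt <- floor(raw)
  rem <- k - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  sample(rep(time_slice_levels(), cnt))
}

# Table-3-like relative unit sizes, largest-remainder rounded to `total`
.unit_sizes <- function(units, total) {
  ref <- c(24, 5, 16, 11, 6, 14, 9)[seq_along(units)]
  raw <- ref / sum(ref) * total
  sizes <- floor(raw)
  rem <- total - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes <- pmax(sizes, 2L)
  while (sum(sizes) > total) {           # rebalance if the floor bumped us up
    k <- which.max(sizes)
    sizes[k] <- sizes[k] - 1L
  }
  stats::setNames(as.integer(sizes), units)
}

# shrink every family template toward the across-family mean template:
# controls how separated the family mean shapes are in coefficient space
.blend_families <- function(fams, alpha) {
  if (alpha >= 1) return(fams)
  mean_coef <- Reduce(`+`, lapply(fams, function(f) f$template$coef)) /
    length(fams)
  lapply(fams, function(f) {
    f$template$coef <- mean_coef + alpha * (f$template$coef - mean_coef)
    f
  })
}

.default_family_map <- function() {
  c("Magdalenian s.l." = "shouldered_point",
    "Epigravettian s.l." = "triangle",
    "ABP/Azilian" = "arch_backed",
    "ABP/FMG" = "arch_backed",
    "FBT/LBI" = "simple_point",
    "TPC" = "tanged_point",
    "Mesolithic" = "trapeze")
}

.tools_trait_names <- function(n) {
  base <- c("simple_point", "tanged_point", "shouldered_point",
            "arch_backed_point", "angle_backed_point", "straight_backed_point",
            "triangle", "trapeze", "backed_bladelet", "zonhoven_point",
            "malaurie_point", "federmesser_point", "ahrensburg_point",
            "swiderian_point", "endscraper_short", "endscraper_long",
            "burin_dihedral", "burin_on_truncation", "borer_bec",
            "truncated_piece", "blade_knife_unretouched", "microburin",
            "geometric_microlith", "retouched_blade")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("tool_trait_%02d", seq_len(n - length(base))))
}

.technology_trait_names <- function(n) {
  base <- c("en_eperon_platform_preparation",
            sprintf("core_reduction_%02d", 1:25),
            sprintf("raw_material_%02d", 1:5),
            sprintf("laminar_blank_%02d", 1:9),
            sprintf("production_goal_%02d", 1:7),
            sprintf("blank_modification_%02d", 1:5))
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("tech_trait_%02d", seq_len(n - length(base))))
}

# one domain's trait matrix: unit archetypes + cell noise + missingness
.simulate_traits <- function(nac_tab, domain, n_traits, cfg) {
  units <- unique(nac_tab$macro_unit[nac_tab$macro_unit != "unassigned"])
  traits <- if (domain == "tools") .tools_trait_names(n_traits) else
    .technology_trait_names(n_traits)
  base <- stats::rbinom(n_traits, 1L, 0.5)
  arch <- sapply(units, function(u) {
    own <- stats::rbinom(n_traits, 1L, 0.5)
    use_own <- stats::runif(n_traits) < cfg$p_in
    ifelse(use_own, own, base)
  })
  rownames(arch) <- traits
  planted <- character(0)
  if (domain == "technology" &&
      "en_eperon_platform_preparation" %in% traits &&
      "Magdalenian s.l." %in% units) {
    # one diagnostically planted trait: unique to the Magdalenian archetype
    # and exempt from flip noise and missingness, emulating a reliably
    # recorded hallmark trait
    arch["en_eperon_platform_preparation", ] <-
      as.integer(colnames(arch) == "Magdalenian s.l.")
    planted <- "en_eperon_platform_preparation"
  }
  vals <- matrix(NA_integer_, nrow(nac_tab), n_traits,
                 dimnames = list(nac_tab$nac_id, traits))
  for (i in seq_len(nrow(nac_tab))) {
    proto <- if (nac_tab$macro_unit[i] == "unassigned") {
      stats::rbinom(n_traits, 1L, 0.5)
    } else {
      arch[, nac_tab$macro_unit[i]]
    }
    flip <- stats::runif(n_traits) < cfg$noise_flip_rate
    cell <- ifelse(flip, 1L - proto, proto)
    cell[stats::runif(n_traits) < cfg$missing_rate] <- NA_integer_
    cell[match(planted, traits)] <- proto[match(planted, traits)]
    vals[i, ] <- cell
  }
  meta <- data.frame(nac_id = nac_tab$nac_id, region = nac_tab$region,
                     time_slices = nac_tab$time_slices,
                     macro_unit = nac_tab$macro_unit,
                     stringsAsFactors = FALSE)
  trait_matrix(vals, meta, domain = domain)
}

#' Simulate a full synthetic dataset with planted structure
#'
#' Generates, under one seed, the complete input bundle of the analysis
#' pipeline: NAC registry with regions, time-slices and macro-unit
#' assignments; two tri-state trait matrices built from per-unit archetypes
#' with flip noise and missingness; sites with coordinates and quality
#' scores; and an outline set drawn from per-unit shape families whose
#' dispersion follows the configured per-slice schedule. Macro-units occupy
#' contiguous blocks of the region grid, which plants spatially
#' autocorrelated trait similarity; a deterministic per-slice drift of the
#' family mean shapes plants a chronological outline signal.
#'
#' @param config a [generator_config()].
#' @return List of class `synthetic_dataset` with elements `tools`,
#'   `technology` ([trait_matrix()]), `outlines` ([outline_set()]), `sites`
#'   (data frame), `map` ([macrounit_map()]), `regions` (data frame of
#'   centroids), `nacs` (registry data frame), `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    ## region grid
    side <- ceiling(sqrt(cfg$n_regions))
    grid <- expand.grid(col = seq_len(side), row = seq_len(side))
    grid <- grid[seq_len(cfg$n_regions), ]
    lon_step <- max(cfg$spatial_decay_km, 300) / 111.32 * 1.4
    lat_step <- max(cfg$spatial_decay_km, 300) / 111.32
    regions <- data.frame(
      region = default_regions()[seq_len(cfg$n_regions)],
      lon = -5 + (grid$col - 1) * lon_step,
      lat = 42 + (grid$row - 1) * lat_step,
      stringsAsFactors = FALSE)

    ## macro-units on contiguous region blocks
    units <- setdiff(macro_unit_levels(), "unassigned")[seq_len(cfg$n_macro_units)]
    sizes <- .unit_sizes(units, cfg$n_nacs - cfg$n_unassigned)
    ord <- order(regions$lon, regions$lat)
    block_sizes <- .unit_sizes(units, cfg$n_regions)
    block_of <- rep(units, block_sizes)[seq_len(cfg$n_regions)]
    region_block <- split(regions$region[ord], block_of[seq_len(cfg$n_regions)])

    ## NAC registry
    nac_unit <- c(rep(units, sizes), rep("unassigned", cfg$n_unassigned))
    n <- length(nac_unit)
    nac_tab <- data.frame(
      nac_id = sprintf("NAC%03d", seq_len(n)),
      macro_unit = nac_unit,
      stringsAsFactors = FALSE)
    nac_tab$region <- vapply(nac_unit, function(u) {
      pool <- if (u == "unassigned") regions$region else region_block[[u]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    slice <- character(n)
    for (u in unique(nac_unit)) {
      idx <- which(nac_unit == u)
      slice[idx] <- .alloc_slices(length(idx), cfg$time_slice_weights)
    }
    nac_tab$time_slices <- slice
    if (cfg$n_multi_slice > 0L) {
      multi <- sample.int(n, cfg$n_multi_slice)
      for (i in multi) {
        r <- match(slice[i], time_slice_levels())
        nxt <- if (r < 4L) r + 1L else r - 1L
        pair <- sort(c(r, nxt))
        nac_tab$time_slices[i] <-
          paste(time_slice_levels()[pair], collapse = "|")
      }
    }

    ## traits
    tools <- withr::with_seed(.hash_seed(cfg$seed, "traits:tools"),
      .simulate_traits(nac_tab, "tools", cfg$trait_counts[["tools"]], cfg))
    technology <- withr::with_seed(.hash_seed(cfg$seed, "traits:technology"),
      .simulate_traits(nac_tab, "technology",
                       cfg$trait_counts[["technology"]], cfg))

    ## sites
    rub <- default_quality_rubric()
    sites <- do.call(rbind, lapply(seq_len(n), function(i) {
      ctr <- regions[regions$region == nac_tab$region[i], ]
      ns <- cfg$sites_per_nac
      jit_km <- matrix(stats::rnorm(2 * ns, 0, cfg$spatial_decay_km / 6), ns)
      sub <- vapply(rub, function(mx) sample.int(mx + 1L, ns, TRUE) - 1L,
                    integer(ns))
      if (ns == 1L) sub <- matrix(sub, nrow = 1L)
      data.frame(
        site_id = sprintf("S_%s_%d", nac_tab$nac_id[i], seq_len(ns)),
        nac_id = nac_tab$nac_id[i], region = nac_tab$region[i],
        lat = ctr$lat + jit_km[, 1] / 111.32,
        lon = ctr$lon + jit_km[, 2] / (111.32 * cos(ctr$lat * pi / 180)),
        chronology = sub[, 1], stratigraphy = sub[, 2],
        integrity = sub[, 3], recency = sub[, 4],
        quality_total = as.integer(rowSums(sub)),
        stringsAsFactors = FALSE)
    }))
    rownames(sites) <- NULL

    ## outlines: balanced per (macro-unit, slice), round-robin over the
    ## unit's NACs present in that slice
    fams <- .blend_families(shape_families(), cfg$family_blend)
    fam_map <- .default_family_map()[units]
    disp <- cfg$shape_dispersion_by_slice
    nac_slices <- strsplit(nac_tab$time_slices, "|", fixed = TRUE)
    outs <- list()
    for (u in units) {
      fam <- fams[[fam_map[[u]]]]
      u_idx <- which(nac_tab$macro_unit == u)
      n_per_slice <- cfg$outlines_per_nac * max(1L, round(length(u_idx) / 4))
      for (s in time_slice_levels()) {
        here <- u_idx[vapply(nac_slices[u_idx], function(z) s %in% z,
                             logical(1))]
        if (length(here) == 0L) next
        rk <- match(s, time_slice_levels())
        drift <- .slice_drift(nrow(fam$template$coef)) *
          cfg$shape_drift_per_slice * (rk - 1)
        blk <- withr::with_seed(
          .hash_seed(cfg$seed, paste0("outl:", u, ":", s)), {
            lapply(seq_len(n_per_slice), function(k) {
              i <- here[((k - 1L) %% length(here)) + 1L]
              nac_sites <- sites[sites$nac_id == nac_tab$nac_id[i], ]
              st <- nac_sites[((k - 1L) %% nrow(nac_sites)) + 1L, ]
              o <- simulate_outline(
                fam, sigma = disp[[s]], drift = drift,
                artefact_id = sprintf("A_%s_%s_%02d", nac_tab$nac_id[i], s, k))
              o$site_id <- st$site_id; o$nac_id <- nac_tab$nac_id[i]
              o$time_slice <- s; o$lat <- st$lat; o$lon <- st$lon
              o
            })
          })
        outs <- c(outs, blk)
      }
    }

    map <- macrounit_map(stats::setNames(nac_tab$macro_unit, nac_tab$nac_id))
    structure(list(tools = tools, technology = technology,
                   outlines = outline_set(outs), sites = sites, map = map,
                   regions = regions, nacs = nac_tab, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d NACs, %d regions, %d outlines, seed %d\n",
    nrow(x$nacs), nrow(x$regions), length(x$outlines), x$config$seed))
  invisible(x)
}
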