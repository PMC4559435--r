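#' Scenario definition for the canned experiments
#'
#' Bundles everything one end-to-end run needs: the synthetic template spec,
#' the species preset, simulation and imaging parameters, and one explicit
#' seed per stochastic stage.
#'
#' @param template a [template_spec()].
#' @param species `"rat"` or `"human"`.
#' @param params a [sim_params()].
#' @param seeds named list of integer seeds: `template`, `reconstruct`,
#'   `latency`, `noise`.
#' @param imaging list with `psf`, `downsample`, `photon_scale`.
#' @param reconstruct_control list passed to [reconstruct()] (e.g.
#'   `max_iter`).
#' @export
scenario <- function(template = template_spec(), species = "rat",
                     params = sim_params(),
                     seeds = list(template = 1, reconstruct = 2,
                                  latency = 3, noise = 4),
                     imaging = list(psf = psf_spec(), downsample = 2,
                                    photon_scale = 100),
                     reconstruct_control = list(max_iter = 2e5)) {
  structure(list(template = template, species = species, params = params,
                 seeds = seeds, imaging = imaging,
                 reconstruct_control = reconstruct_control),
            class = "ryr_scenario")
}

#' Validate a scenario
#'
#' Checks units, the explicit-scheme stability bound, seed presence and
#' preset consistency. Returns a character vector of violations (empty when
#' the scenario is valid) rather than erroring.
#'
#' @param sc an [scenario()].
#' @param buffers buffer set the simulation will use.
#' @export
validate_scenario <- function(sc, buffers = default_buffers()) {
  v <- character(0)
  need <- c("template", "reconstruct", "latency", "noise")
  missing <- setdiff(need, names(sc$seeds))
  if (length(missing))
    v <- c(v, sprintf("missing seed(s): %s", paste(missing, collapse = ", ")))
  if (!sc$species %in% c("rat", "human"))
    v <- c(v, sprintf("unknown species preset '%s'", sc$species))
  d_max <- max(sc$params$d_ca,
               vapply(buffers, function(b) b$diffusivity, numeric(1)))
  h <- sc$template$voxel_size
  bound <- h^2 / (6 * d_max)
  if (sc$params$dt > bound)
    v <- c(v, sprintf(
      "dt = %g ms violates the stability bound %.3g ms at voxel %g um",
      sc$params$dt, bound, h))
  if (sc$params$release_radius < h)
    v <- c(v, sprintf(
      "release radius %g um is below the voxel size %g um",
      sc$params$release_radius, h))
  fr <- sc$template$myofibril_fraction + sc$template$mitochondria_fraction
  if (fr >= 1) v <- c(v, "area fractions sum to >= 1")
  v
}

# build template -> window -> reconstructed pattern -> sites for a scenario
prepare_scenario <- function(sc) {
  vol <- make_template(sc$template, seed = sc$seeds$template)
  win <- build_window(vol)
  planes <- zdisc_planes(vol)
  preset <- species_presets(sc$species,
                            cross_section_area = sc$template$cross_section_area)
  rec <- do.call(reconstruct,
                 c(list(targets = preset$targets, window = win,
                        planes = planes, seed = sc$seeds$reconstruct),
                   sc$reconstruct_control))
  sites <- mark_release_sites(rec$pattern, vol,
                              radius = sc$params$release_radius)
  for (i in seq_along(sites)) sites[[i]]$current_pA <- preset$current_pA
  ext <- volume_extent(vol)
  list(volume = vol, window = win, planes = planes, preset = preset,
       recon = rec, sites = sites,
       line = c(0, ext[2] / 2, ext[1], ext[2] / 2))
}

run_one_sim <- function(sc, prep, sites = NULL, latency_seed = NULL) {
  params <- sc$params
  params$seed <- if (is.null(latency_seed)) sc$seeds$latency else latency_seed
  simulate_transient(prep$volume, if (is.null(sites)) prep$sites else sites,
                     params = params, record = 1, record_slice = 1)
}

#' Run one of the canned experiments
#'
#' * `heterogeneity`: default scenario end-to-end; reports the transient
#'   trace, spatial heterogeneity metrics of free Ca and F/F0 at the end
#'   time, the line scan, and the correlation between rendered line
#'   intensity and local cluster density.
#' * `distributions`: repeats the reconstruction under `n_seeds` seeds with
#'   identical release timing; reports the pairwise relative spread of the
#'   volume-averaged F/F0 traces (seed-invariance of the bulk transient) and
#'   the locations of the hottest voxels (which move with the distribution).
#' * `orphans`: silences increasing numbers of neighbouring clusters and
#'   reports the local fluorescence drop and the silenced-group span.
#' * `species`: rat versus human presets on the same template with
#'   release-current compensation; reports cluster counts, per-cluster and
#'   total currents and both traces.
#'
#' @param name experiment name.
#' @param sc an [scenario()].
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @param n_seeds reconstruction seeds for `distributions`.
#' @param orphan_k numbers of silenced clusters for `orphans`.
#' @return a report list; also written as JSON + CSVs when `out_dir` given.
#' @export
run_experiment <- function(name = c("heterogeneity", "distributions",
                                    "orphans", "species"),
                           sc = scenario(), out_dir = NULL,
                           n_seeds = 3, orphan_k = c(0, 2, 4)) {
  name <- match.arg(name)
  viol <- validate_scenario(sc)
  if (length(viol))
    abort(paste0("invalid scenario: ", paste(viol, collapse = "; ")))
  prep <- prepare_scenario(sc)
  report <- list(experiment = name, species = sc$species,
                 n_clusters = prep$preset$n,
                 current_pA = prep$preset$current_pA)

  if (name == "heterogeneity") {
    sim <- run_one_sim(sc, prep)
    ff0 <- f_over_f0(sim)
    mask <- array(sim$volume$labels != LBL_MITO, dim(sim$volume$labels))
    report$trace <- sim$trace
    report$metrics_ff0 <- heterogeneity_metrics(ff0, mask)
    report$metrics_ca <- heterogeneity_metrics(sim_field(sim, "ca"), mask)
    ls <- line_scan(sim, prep$line, psf = sc$imaging$psf,
                    downsample = sc$imaging$downsample,
                    photon_scale = sc$imaging$photon_scale,
                    seed = sc$seeds$noise)
    report$linescan <- ls
    dens <- cluster_density_profile(prep$recon$pattern, prep$line,
                                    z = prep$planes[1])
    last <- ls[ls$time == max(ls$time), ]
    report$density_intensity_cor <- cor(
      approx(last$position, last$rendered, xout = dens$position,
             rule = 2)$y,
      dens$density, method = "spearman")
  } else if (name == "distributions") {
    seeds <- sc$seeds$reconstruct + seq_len(n_seeds) - 1
    runs <- lapply(seeds, function(s) {
      sc2 <- sc
      sc2$seeds$reconstruct <- s
      prep2 <- prepare_scenario(sc2)
      list(prep = prep2, sim = run_one_sim(sc2, prep2))
    })
    traces <- lapply(runs, function(r) r$sim$trace$f_f0)
    pairs <- utils::combn(n_seeds, 2)
    rel <- apply(pairs, 2, function(p)
      max(abs(traces[[p[1]]] - traces[[p[2]]]) /
            pmax(traces[[p[1]]], 1e-12)))
    report$max_pairwise_rel_diff <- max(rel)
    report$traces <- tibble(
      seed = rep(seeds, each = length(runs[[1]]$sim$trace$time)),
      time = rep(runs[[1]]$sim$trace$time, n_seeds),
      f_f0 = unlist(traces))
    report$hotspots <- t(vapply(runs, function(r) {
      arr <- sim_field(r$sim, "ca", fill = -Inf)
      w <- arrayInd(which.max(arr), dim(arr))
      (w - 0.5) * r$sim$domain$voxel_size
    }, numeric(3)))
  } else if (name == "orphans") {
    ext <- volume_extent(prep$volume)
    center <- c(ext[1] / 2, ext[2] / 2, prep$planes[1])
    rows <- list()
    for (k in orphan_k) {
      sites_k <- deactivate_clusters(prep$sites, center, k)
      sim <- run_one_sim(sc, prep, sites = sites_k)
      ls <- line_scan(sim, prep$line, psf = sc$imaging$psf,
                      downsample = sc$imaging$downsample,
                      photon_scale = sc$imaging$photon_scale,
                      seed = sc$seeds$noise)
      last <- ls[ls$time == max(ls$time), ]
      rows[[length(rows) + 1]] <- tibble(
        k = k, span_diameter = attr(sites_k, "span_diameter"),
        f_f0_mean = sim$trace$f_f0[nrow(sim$trace)],
        profile_min = min(last$rendered))
      if (k == orphan_k[1]) report$baseline_trace <- sim$trace
    }
    report$orphans <- bind_rows(rows)
  } else if (name == "species") {
    sc_h <- sc
    sc_h$species <- "human"
    prep_h <- prepare_scenario(sc_h)
    sim_r <- run_one_sim(sc, prep)
    sim_h <- run_one_sim(sc_h, prep_h)
    report$rat <- list(n = prep$preset$n,
                       current_pA = prep$preset$current_pA,
                       total_pA = prep$preset$n * prep$preset$current_pA,
                       trace = sim_r$trace)
    report$human <- list(n = prep_h$preset$n,
                         current_pA = prep_h$preset$current_pA,
                         total_pA = prep_h$preset$n * prep_h$preset$current_pA,
                         trace = sim_h$trace)
    report$total_current_rel_diff <-
      abs(report$rat$total_pA - report$human$total_pA) / report$rat$total_pA
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# write a report's tabular members as CSV and the scalars as JSON
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- list()
  for (nm in names(report)) {
    x <- report[[nm]]
    if (inherits(x, "data.frame")) {
      write.csv(x, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
    } else if (is.atomic(x) && length(x) <= 9) {
      scalars[[nm]] <- x
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(scalars, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
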