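# End-to-end runs: validate a YAML config, execute the selected analyses,
# write tabular outputs and a machine-readable summary with provenance.

.analysis_names <- c("rdf", "shells", "densmap", "coloc", "orient", "area")

#' Validate a run configuration
#'
#' Reads a YAML run configuration, fills in defaults mirroring the standard
#' analysis parameters (0.75 nm first-shell cutoff, 0.4-0.8 and 0.8-1.1 nm
#' coordination shells, the eight angular sectors) and validates it,
#' reporting all problems at once.
#'
#' Schema (YAML):
#' \preformatted{
#' seed: 1
#' output_dir: out
#' species_map: bundled            # or a path
#' input:
#'   paths: [a.gro, b.gro]         # either file paths ...
#'   generator: {mode: csr, ...}   # ... or generator_params arguments
#' analyses:
#'   rdf:    {species_a: CHOL, species_b: CHOL, bin_width: 0.01, r_max: 2.5}
#'   shells: {species_a: CHOL, species_b: CHOL,
#'            first: [0.4, 0.8], second: [0.8, 1.1]}
#'   densmap: {reference: CHOL, target: CHOL, extent: 2.5, bin: 0.05}
#'   coloc:  {sterol: CHOL, lipid: DSPC, cutoff: 0.75, bin_width: 5}
#'   orient: {sterol: CHOL, r_lo: 0.8, r_hi: 1.1, bin_width: 5}
#'   area: {}
#' }
#'
#' @param path Path to the YAML config (or an already-parsed list).
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) path else {
    if (!file.exists(path)) {
      so_stop(sprintf("config file not found: %s", path), "sterolorder_config_error")
    }
    yaml::read_yaml(path)
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  cfg <- list(seed = raw$seed %||% 1L,
              output_dir = raw$output_dir %||% "sterolorder_out",
              species_map = raw$species_map %||% "bundled")
  if (identical(cfg$species_map, "bundled")) {
    cfg$species_map_path <- default_species_map_path()
  } else {
    cfg$species_map_path <- cfg$species_map
    if (!file.exists(cfg$species_map_path)) {
      note(sprintf("species map not found: %s", cfg$species_map_path))
    }
  }
  input <- raw$input
  if (is.null(input) || (is.null(input$paths) && is.null(input$generator))) {
    note("input must provide either 'paths' or 'generator'")
  }
  if (!is.null(input$paths)) {
    missing <- input$paths[!file.exists(unlist(input$paths))]
    if (length(missing)) {
      note(sprintf("input path(s) not found: %s", paste(missing, collapse = ", ")))
    }
    cfg$input <- list(paths = unlist(input$paths))
  } else if (!is.null(input$generator)) {
    gp <- tryCatch(do.call(generator_params,
                           c(input$generator,
                             if (is.null(input$generator$seed)) list(seed = cfg$seed))),
                   error = function(e) {
                     note(sprintf("generator: %s", conditionMessage(e)))
                     NULL
                   })
    cfg$input <- list(generator = gp)
  }
  an <- raw$analyses
  if (is.null(an) || !length(an)) {
    note("at least one analysis must be selected under 'analyses'")
    an <- list()
  }
  unknown <- setdiff(names(an), .analysis_names)
  if (length(unknown)) {
    note(sprintf("unknown analysis name(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.analysis_names, collapse = ", ")))
  }
  defaults <- list(
    rdf = list(species_a = "CHOL", species_b = "CHOL", bin_width = 0.01,
               r_max = 2.5),
    shells = list(species_a = "CHOL", species_b = "CHOL",
                  first = c(0.4, 0.8), second = c(0.8, 1.1)),
    densmap = list(reference = "CHOL", target = "CHOL", extent = 2.5,
                   bin = 0.05),
    coloc = list(sterol = "CHOL", lipid = "DSPC", cutoff = 0.75, bin_width = 5),
    orient = list(sterol = "CHOL", r_lo = 0.8, r_hi = 1.1, bin_width = 5),
    area = list())
  cfg$analyses <- list()
  for (nm in intersect(names(an), .analysis_names)) {
    spec <- utils::modifyList(defaults[[nm]], as.list(an[[nm]]))
    if (nm == "shells") {
      sh <- spec[setdiff(names(spec), c("species_a", "species_b"))]
      sh <- lapply(sh, unlist)
      ok <- tryCatch({ validate_shells(sh); TRUE },
                     error = function(e) { note(sprintf("shells: %s", conditionMessage(e))); FALSE })
      if (ok) spec$ranges <- sh
    }
    if (nm == "orient" && spec$r_hi <= spec$r_lo) {
      note("orient: r_hi must exceed r_lo")
    }
    cfg$analyses[[nm]] <- spec
  }
  if (length(problems)) {
    so_stop(paste0("invalid run configuration:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "sterolorder_config_error")
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured analysis pipeline
#'
#' Loads or generates the input snapshots, runs every selected analysis,
#' writes one delimited text file per analysis plus a JSON summary
#' (`summary.json`) carrying provenance metadata (config hash, seed,
#' package version) into the output directory. Deterministic for a given
#' config and seed.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   YAML config.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- load_species_map(config$species_map_path)
  snaps <- if (!is.null(config$input$paths)) {
    read_snapshots(config$input$paths, sm)
  } else {
    generate_leaflet(config$input$generator)$snapshots
  }
  snaps <- lapply(snaps, assign_leaflets, species_map = sm)

  cfg_tmp <- tempfile()
  writeLines(yaml::as.yaml(unclass(config)), cfg_tmp)
  summary <- list(provenance = list(
    package = "sterolorder",
    version = as.character(utils::packageVersion("sterolorder")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    n_frames = length(snaps)))
  unlink(cfg_tmp)

  outfile <- function(name) file.path(config$output_dir, name)
  tsv <- function(df, name) {
    utils::write.table(df, outfile(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (nm in names(config$analyses)) {
    a <- config$analyses[[nm]]
    res <- switch(nm,
      rdf = {
        prof <- lateral_rdf(snaps, a$species_a, a$species_b, sm,
                            bin_width = a$bin_width, r_max = a$r_max)
        tsv(as.data.frame(prof), "rdf.tsv")
        list(peak_r = prof$r_mid[which.max(prof$g)],
             peak_g = max(prof$g, na.rm = TRUE))
      },
      shells = {
        so <- shell_density_ratio(snaps, a$species_a, a$species_b, sm,
                                  shells = a$ranges)
        tsv(as.data.frame(so), "shells.tsv")
        stats::setNames(as.list(so$ratio), paste0(so$shell, "_shell_ratio"))
      },
      densmap = {
        dm <- accumulate_density_map(snaps, a$reference, a$target, sm,
                                     extent = a$extent, bin = a$bin)
        write_density_map(dm, outfile("densmap.txt"))
        pk <- find_peaks(dm, radial_band = c(0.7, 1.3), min_separation = 0.3)
        tsv(as.data.frame(pk), "densmap_peaks.tsv")
        list(n_peaks = nrow(pk),
             peaks = lapply(seq_len(nrow(pk)), function(i) {
               list(phi = pk$phi[i], r = pk$r[i], sector = pk$sector[i])
             }))
      },
      coloc = {
        dist <- theta90_distribution(snaps, a$sterol, a$lipid, sm,
                                     bin_width = a$bin_width, cutoff = a$cutoff)
        tsv(as.data.frame(dist), "theta90.tsv")
        cs <- chain_separation_summary(snaps, a$lipid, sm,
                                       sterol_species = a$sterol,
                                       cutoff = a$cutoff)
        list(n_pairs = attr(dist, "n_pairs"),
             modal_theta90 = dist$mid[which.max(dist$count)],
             chain_separation_mean = cs$mean, chain_separation_sd = cs$sd)
      },
      orient = {
        sod <- sector_orientation_distributions(snaps, a$sterol, sm,
                                                r_range = c(a$r_lo, a$r_hi),
                                                bin_width = a$bin_width)
        ord <- c(attr(sod, "preferred"), setdiff(names(sod), attr(sod, "preferred")))
        for (sec in ord) {
          tsv(as.data.frame(sod[[sec]]), sprintf("orient_%s.tsv", sec))
        }
        lapply(sod, function(d) attr(d, "n_pairs"))
      },
      area = {
        ar <- mean_lateral_area(snaps)
        list(mean_area = ar$mean, sd_area = ar$sd, n_frames = ar$n_frames)
      })
    summary[[nm]] <- res
  }
  jsonlite::write_json(summary, outfile("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
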