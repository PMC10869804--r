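.known_config_keys <- c("seed", "output_dir", "numbering_offset", "ordered_region",
                        "structure", "ensemble", "sasa", "csp", "fp", "melt", "urea",
                        "conservation", "stages")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file holding one). Unknown
#' keys are rejected outright; every referenced input file must exist before
#' any computation starts.
#'
#' @param config named list or path to a YAML file.
#' @return the validated configuration list (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$output_dir)) stop("config must set output_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  config$numbering_offset <- as.integer(config$numbering_offset %||% 0L)
  paths <- c(config$structure$path, config$ensemble$path, config$csp$free, config$csp$bound,
             config$fp$path, config$melt$path, config$urea$path,
             config$conservation$path)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) stop("input file(s) not found: ", paste(missing, collapse = ", "))
  default_stages <- c(
    if (!is.null(config$structure)) c("surface", "geometry"),
    if (!is.null(config$ensemble) || !is.null(config$structure)) "ensemble",
    if (!is.null(config$csp)) "csp",
    if (!is.null(config$fp) || !is.null(config$melt) || !is.null(config$urea)) "fit",
    if (!is.null(config$conservation)) "conserve")
  config$stages <- config$stages %||% default_stages
  bad <- setdiff(config$stages, c("surface", "ensemble", "geometry", "csp", "fit", "conserve"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!length(config$stages)) stop("no stage enabled by this configuration")
  config
}

run_stage <- function(report, name, fun) {
  t0 <- proc.time()["elapsed"]
  res <- tryCatch(fun(), error = function(e) {
    list(.error = conditionMessage(e))
  })
  res$elapsed_s <- round(unname(proc.time()["elapsed"] - t0), 3)
  report[[name]] <- res
  report
}

#' Run the full characterization pipeline
#'
#' Executes the enabled stages in dependency order (structure-dependent
#' stages first, then shift, curve and alignment analyses, which are
#' mutually independent), collects every stage's numeric results into a
#' report and writes `report.json`, a human-readable `report.txt` and the
#' resolved configuration into the output directory. A failing stage is
#' recorded with its error message; independent stages still run.
#'
#' @param config configuration list or YAML path, see
#'   [validate_run_config()].
#' @return the report list (class `dimerlab_report`), invisibly the same
#'   object that was written to JSON.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  map <- numbering_map(config$numbering_offset)
  ordered <- config$ordered_region %||% list(start = 12L, end = 54L)
  rng <- c(ordered$start, ordered$end)
  params <- sasa_params(probe_radius = config$sasa$probe_radius %||% 1.4,
                        n_points = config$sasa$n_points %||% 960L)
  report <- list(provenance = list(
    package = "dimerlab",
    version = as.character(utils::packageVersion("dimerlab")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  struct <- NULL
  if (!is.null(config$structure)) {
    struct <- read_structure(config$structure$path)
  }
  if ("surface" %in% config$stages && !is.null(struct)) {
    report <- run_stage(report, "surface", function() {
      ca <- config$structure$chains_a %||% unique(struct$atoms$chain)[1]
      cb <- config$structure$chains_b %||% unique(struct$atoms$chain)[2]
      sel <- selection(chains = ca, ranges = rng, atom_class = "heavy")
      protomer_sasa <- compute_sasa(apply_selection(struct, 1L, sel, map), params)
      iface <- interface_analysis(struct, 1L, ca, cb, params,
                                  cutoff = config$sasa$interface_cutoff %||% 0.1,
                                  map = map)
      sb <- find_salt_bridges(struct, 1L, map = map, params = params)
      hb <- find_hbonds(struct, 1L, map = map)
      list(protomer_asa_ordered = protomer_sasa$total,
           buried_total_per_chain = as.list(iface$buried_total),
           buried_total_complexwide = iface$buried_total_complexwide,
           n_interface_residues = as.list(iface$n_interface),
           n_salt_bridges = nrow(sb),
           salt_bridges = sb,
           n_backbone_hbonds = nrow(hb),
           n_interchain_hbonds = sum(hb$inter_chain))
    })
  }
  ens_struct <- if (!is.null(config$ensemble$path)) read_structure(config$ensemble$path) else struct
  if ("ensemble" %in% config$stages && !is.null(ens_struct) && n_models(ens_struct) > 1L) {
    report <- run_stage(report, "ensemble", function() {
      sel <- selection(ranges = rng, atom_class = "backbone")
      bb <- ensemble_rmsd(ens_struct, sel, map = map)
      sel$atom_class <- "heavy"
      hv <- ensemble_rmsd(ens_struct, sel, map = map)
      list(n_models = n_models(ens_struct),
           backbone_rmsd_to_mean = bb$mean_rmsd,
           heavy_rmsd_to_mean = hv$mean_rmsd)
    })
  }
  if ("geometry" %in% config$stages && !is.null(struct)) {
    report <- run_stage(report, "geometry", function() {
      ss <- assign_secondary_structure(struct, 1L, map)
      ch <- unique(struct$atoms$chain)[1]
      hel <- ss$segments[ss$segments$kind == "helix" & ss$segments$chain == ch, ]
      ang <- NA_real_
      if (nrow(hel) >= 2) {
        ax <- lapply(seq_len(2), function(i) {
          sel <- selection(chains = ch, ranges = c(hel$start[i], hel$end[i]),
                           atom_class = "calpha")
          ca <- apply_selection(struct, 1L, sel, map)
          helix_axis(cbind(ca$x, ca$y, ca$z))
        })
        ang <- interhelix_angle(ax[[1]], ax[[2]])
      }
      list(segments = ss$segments,
           n_helices_per_chain = nrow(hel),
           n_strands_per_chain = sum(ss$segments$kind == "strand" & ss$segments$chain == ch),
           interhelix_angle_deg = ang)
    })
  }
  if ("csp" %in% config$stages && !is.null(config$csp)) {
    report <- run_stage(report, "csp", function() {
      cfg <- csp_config(nitrogen_weight = config$csp$nitrogen_weight %||% 0.14,
                        threshold = config$csp$threshold %||% 0.05,
                        formula_variant = config$csp$formula_variant %||% "weight_squared_with_shift")
      res <- compute_csp(read_shift_table(config$csp$free),
                         read_shift_table(config$csp$bound), cfg)
      region <- config$csp$region
      mapres <- NULL
      if (!is.null(struct)) {
        mapres <- map_csp(res, struct, map,
                          path = file.path(config$output_dir, "csp_annotated.pdb"),
                          region = if (!is.null(region)) c(region$start, region$end))
      }
      list(n_residues = nrow(res$csp),
           n_significant = sum(res$csp$significant),
           significant_residues = res$csp$native_num[res$csp$significant],
           max_csp = max(res$csp$d),
           unmatched_bound = res$unmatched_bound,
           fraction_in_region = if (!is.null(mapres)) mapres$fraction_in_region)
    })
  }
  if ("fit" %in% config$stages) {
    report <- run_stage(report, "fit", function() {
      out <- list()
      if (!is.null(config$fp)) {
        d <- utils::read.csv(config$fp$path)
        fit <- fit_fp_binding(d[[1]], d[[2]],
                              model = config$fp$model %||% "hyperbolic",
                              tracer_conc = config$fp$tracer_conc %||% 0.01)
        out$kd_uM <- fit$kd
        out$kd_se_uM <- fit$kd_se
      }
      if (!is.null(config$melt)) {
        d <- utils::read.csv(config$melt$path)
        fit <- tryCatch(fit_two_state_thermal(d[[1]], d[[2]]),
                        dimerlab_no_transition = function(e) NULL)
        out$tm_C <- if (is.null(fit)) NA_real_ else fit$midpoint
        out$tm_se_C <- if (is.null(fit)) NA_real_ else fit$midpoint_se
      }
      if (!is.null(config$urea)) {
        d <- utils::read.csv(config$urea$path)
        fit <- tryCatch(fit_two_state_chemical(d[[1]], d[[2]]),
                        dimerlab_no_transition = function(e) NULL)
        out$cm_M <- if (is.null(fit)) NA_real_ else fit$midpoint
        out$m_value <- if (is.null(fit)) NA_real_ else fit$m_value
      }
      out
    })
  }
  if ("conserve" %in% config$stages && !is.null(config$conservation)) {
    report <- run_stage(report, "conserve", function() {
      msa <- read_alignment(config$conservation$path)
      refid <- config$conservation$reference_id %||% msa$ids[1]
      st <- column_stats(msa, refid)
      fl <- flag_conserved(st, threshold = config$conservation$threshold %||% 0.80)
      list(n_sequences = length(msa$ids), n_columns = msa$width,
           n_flagged = nrow(fl), flagged = fl,
           consensus = consensus(msa))
    })
  }
  class(report) <- "dimerlab_report"
  write_report(report, config)
  invisible(report)
}

report_to_json_list <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

write_report <- function(report, config) {
  out <- config$output_dir
  cfg_path <- file.path(out, "config_resolved.yaml")
  yaml::write_yaml(config, cfg_path)
  report$provenance$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(report_to_json_list(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE, null = "null")
  txt <- utils::capture.output(print_report(report))
  writeLines(txt, file.path(out, "report.txt"))
  invisible(report)
}

print_report <- function(report) {
  cat("dimerlab pipeline report\n")
  cat("========================\n")
  for (nm in names(report)) {
    cat("\n[", nm, "]\n", sep = "")
    block <- report[[nm]]
    for (k in names(block)) {
      v <- block[[k]]
      if (is.data.frame(v)) {
        cat("  ", k, ": ", nrow(v), " rows\n", sep = "")
      } else if (is.atomic(v) && length(v) <= 12) {
        cat("  ", k, ": ", paste(format(v, digits = 6), collapse = ", "), "\n", sep = "")
      } else if (is.list(v)) {
        cat("  ", k, ": ", paste(names(v), format(unlist(v), digits = 6),
                                 sep = "=", collapse = ", "), "\n", sep = "")
      }
    }
  }
  invisible(report)
}

#' @export
print.dimerlab_report <- function(x, ...) print_report(x)

#' Check a pipeline report against the shipped schema
#'
#' The schema (`inst/schema/report_schema.json`) is a minimal
#' required-keys/type document; this checker verifies the provenance block
#' and that every stage block is a named list whose error field, when
#' present, is a string.
#'
#' @param report a [run_pipeline()] result (or its parsed JSON).
#' @return TRUE, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "dimerlab"))
  req <- unlist(schema$required)
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report is missing required block(s): ", paste(miss, collapse = ", "))
  prov_req <- unlist(schema$properties$provenance$required)
  miss <- setdiff(prov_req, names(report$provenance))
  if (length(miss)) stop("provenance is missing: ", paste(miss, collapse = ", "))
  for (nm in setdiff(names(report), "provenance")) {
    if (!is.list(report[[nm]])) stop("stage block '", nm, "' is not an object")
    if (!is.null(report[[nm]]$.error) && !is.character(report[[nm]]$.error)) {
      stop("stage block '", nm, "' has a non-string error field")
    }
  }
  TRUE
}
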