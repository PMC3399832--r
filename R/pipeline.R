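# End-to-end orchestration: structure -> coarse-grained ensemble ->
# correlation / hinge / omega / state / network / conservation report.

#' Pipeline configuration
#'
#' Collects the per-stage parameter blocks with their reference defaults
#' (Kovacs C = 40 kcal/mol/A^2, r* = 3.8 A, DCCM threshold 0.35 with
#' sequence separation 10, chained-correlation threshold 0.5 to depth 5,
#' state cutoffs 0.6/1.0 nm and 20/35 %, contact cutoffs 0.45/0.55 nm with
#' 20 % persistence).
#'
#' @param input one of: a [ca_structure()], an [ensemble()], or a PDB path.
#' @param loop_range length-2 residue-number range of the acidic loop.
#' @param cys_residue catalytic cysteine residue number (optional; state
#'   classification is skipped without it).
#' @param chain_roots residue numbers used as chained-correlation roots
#'   (default: hydrophobic residues inside `loop_range`).
#' @param alignment optional [alignment_block()] for conservation scoring.
#' @param method sampler used when `input` is a structure
#'   (`"nma"`, `"bd"`, `"dmd"`).
#' @param n_frames frames to sample (NMA) (default 2000).
#' @param seed master seed; every stochastic stage derives from it.
#' @param cg,bd,dmd,net,thresholds,criteria parameter blocks
#'   ([cg_params()], [bd_params()], [dmd_params()], [network_params()],
#'   [state_thresholds()], [omega_criteria()]).
#' @param dccm_window window length in frames (`NULL` = single window).
#' @param model_policy PDB model policy when `input` is a path.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, loop_range, cys_residue = NULL,
                            chain_roots = NULL, alignment = NULL,
                            method = c("nma", "bd", "dmd"),
                            n_frames = 2000, seed = 1,
                            cg = cg_params(), bd = bd_params(),
                            dmd = dmd_params(), net = network_params(),
                            thresholds = state_thresholds(),
                            criteria = omega_criteria(),
                            dccm_window = NULL,
                            model_policy = "all") {
  method <- match.arg(method)
  structure(list(input = input, loop_range = loop_range,
                 cys_residue = cys_residue, chain_roots = chain_roots,
                 alignment = alignment, method = method, n_frames = n_frames,
                 seed = seed, cg = cg, bd = bd, dmd = dmd, net = net,
                 thresholds = thresholds, criteria = criteria,
                 dccm_window = dccm_window, model_policy = model_policy),
            class = "pipeline_config")
}

#' Run the full characterization pipeline
#'
#' Stages: (1) load/sample an ensemble; (2) flexibility profile (PCA-filtered
#' RMSF + B-factors); (3) PCA diagnostics; (4) DCCM and chained correlations;
#' (5) hinge prediction; (6) omega-loop classification; (7) conformational
#' states; (8) conservation scores and consensus (when an alignment is
#' given).  Stage failures are caught and recorded; the report is
#' deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with one element per stage plus
#'   `parameters` and `failures`.
#' @export
run_pipeline <- function(config) {
  failures <- list()
  report <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
    report[[name]] <<- res
    res
  }

  ens <- run_stage("ensemble", {
    inp <- config$input
    if (is.character(inp)) inp <- read_pdb(inp, model_policy = config$model_policy)
    if (inherits(inp, "ensemble")) {
      inp
    } else {
      net <- build_network(inp, config$cg, method = config$method,
                           dmd = config$dmd)
      switch(config$method,
        nma = nma_ensemble(anm_modes(net), config$cg,
                           n_frames = config$n_frames, seed = config$seed),
        bd = {
          p <- config$bd; p$seed <- config$seed
          bd_simulate(net, p, config$cg)
        },
        dmd = {
          p <- config$dmd; p$seed <- config$seed
          dmd_simulate(net, p, config$cg)
        }
      )
    }
  })
  if (is.null(ens)) {
    return(structure(list(failures = failures, parameters = config),
                     class = "pipeline_report"))
  }
  ca_ens <- if (ens$ref$calpha_only) ens else calpha_ensemble(ens)

  profile <- run_stage("flexibility", rmsf_profile(ca_ens))
  run_stage("pca", pca_ensemble(ca_ens))
  d <- run_stage("dccm", dccm(ca_ens, window_frames = config$dccm_window))
  if (!is.null(d)) {
    run_stage("chains", {
      resno <- ca_ens$ref$res$resno
      roots <- config$chain_roots
      if (is.null(roots)) {
        inloop <- resno >= config$loop_range[1] & resno <= config$loop_range[2]
        roots <- resno[inloop & ca_ens$ref$res$resname %in% .HYDROPHOBIC_RES]
        if (length(roots) == 0) roots <- resno[inloop]
      }
      chained_correlations(d, match(roots, resno))
    })
  }
  hinges <- if (!is.null(profile)) {
    run_stage("hinges", predict_hinges(profile, config$loop_range))
  }
  run_stage("omega", {
    cand <- if (!is.null(hinges) && nrow(hinges$candidates) > 0 &&
                any(hinges$candidates$side == "N") &&
                any(hinges$candidates$side == "C")) {
      nc <- hinges$candidates
      as.matrix(expand.grid(
        utils::head(nc$resno[nc$side == "N"], 3),
        utils::head(nc$resno[nc$side == "C"], 3)
      ))
    } else {
      matrix(config$loop_range, ncol = 2)
    }
    classify_omega_loop(ca_ens, config$loop_range, cand, config$criteria)
  })
  if (!is.null(config$cys_residue)) {
    run_stage("states", classify_states(ens, config$cys_residue,
                                        config$loop_range, config$thresholds))
    if (!ens$ref$calpha_only) {
      run_stage("contacts", {
        recs <- detect_contacts(ens, list(resno = seq(config$loop_range[1],
                                                      config$loop_range[2])),
                                list(resno = ens$ref$res$resno),
                                kind = "saltbridge", params = config$net)
        filter_by_persistence(recs, config$net)
      })
    }
  }
  if (!is.null(config$alignment)) {
    run_stage("conservation", score_columns(config$alignment))
    run_stage("consensus", consensus_pattern(config$alignment, 0.70))
  }
  structure(c(report, list(failures = failures, parameters = config)),
            class = "pipeline_report")
}

#' @noRd
calpha_ensemble <- function(ens) {
  ca <- as_calpha(ens$ref)
  cols <- as.vector(t(outer(ens$ref$res$ca_atom, 1:3,
                            function(a, k) 3 * (a - 1) + k)))
  ensemble(ca, ens$xyz[, cols, drop = FALSE],
           frame_spacing = ens$frame_spacing, provenance = ens$provenance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  stages <- setdiff(names(x), c("failures", "parameters"))
  cat("pipeline_report with stages:", paste(stages, collapse = ", "), "\n")
  if (length(x$failures)) {
    cat("failed stages:\n")
    for (nm in names(x$failures)) cat(sprintf("  %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (scalars, tables, verdicts) plus CSV files for the
#' flexibility profile, the averaged DCCM and the chained-correlation edge
#' list.  Output is deterministic for a fixed seed.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the JSON report.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(failures = report$failures)
  if (!is.null(report$flexibility)) {
    utils::write.csv(report$flexibility, file.path(dir, "flexibility.csv"),
                     row.names = FALSE)
    js$flexibility <- list(max_bfactor = max(report$flexibility$bfactor),
                           max_residue = report$flexibility$resno[
                             which.max(report$flexibility$bfactor)])
  }
  if (!is.null(report$pca)) {
    js$pca <- list(cum_var_3 = report$pca$cum_var[min(3, length(report$pca$cum_var))],
                   cosine_content = report$pca$cosine_content,
                   rmsip_halves = report$pca$rmsip_halves)
  }
  if (!is.null(report$dccm)) {
    utils::write.csv(report$dccm$average, file.path(dir, "dccm.csv"),
                     row.names = FALSE)
    js$dccm <- list(n_significant = sum(report$dccm$significant) / 2,
                    consistency = report$dccm$consistency)
  }
  if (!is.null(report$chains)) {
    utils::write.csv(report$chains$edges, file.path(dir, "chains.csv"),
                     row.names = FALSE)
    js$chains <- list(n_chained = nrow(report$chains$edges),
                      deep_partners = report$chains$deep_partners)
  }
  if (!is.null(report$hinges)) {
    js$hinges <- report$hinges$candidates
  }
  if (!is.null(report$omega)) {
    js$omega <- list(verdict = report$omega$verdict,
                     best_pair = report$omega$best_pair,
                     pairs = report$omega$pairs[, setdiff(names(report$omega$pairs),
                                                          "distances")])
  }
  if (!is.null(report$states)) {
    js$states <- list(fractions = report$states$fractions,
                      agreement = report$states$agreement,
                      buried10 = report$states$buried10_fraction)
  }
  if (!is.null(report$contacts)) {
    js$contacts <- report$contacts$records
  }
  if (!is.null(report$conservation)) {
    utils::write.csv(report$conservation, file.path(dir, "conservation.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$consensus)) {
    js$consensus <- attr(report$consensus, "pattern")
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
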