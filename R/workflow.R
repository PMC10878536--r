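#' Run the full integration workflow from a configuration
#'
#' Orchestrates the stages preprocess (or simulate), fit, select, permute,
#' drugnet and enrich in order, writing every table as TSV and every
#' parameter blob as JSON into the configured output directory, together
#' with a manifest (stage, status, outputs, md5 checksums, wall time) and a
#' timestamped run log. Stages whose inputs are not configured are marked
#' `"skipped"`; a failing stage aborts the run with its name in the error.
#' Re-running with an identical configuration (and seed) reproduces
#' identical numeric outputs.
#'
#' @param config Path to a YAML file or an equivalent named list. Top-level
#'   keys: `seed`, `output_dir`, then per-stage blocks `simulate` (keys
#'   `p`, `preset`, optional generator overrides) or `preprocess` (keys
#'   `expr` named list of TSV paths, `meta`, `map`, `reference`,
#'   `iqr`), `model` (`r`, `r_k`, `n_starts`, `max_iter`, `tol`), `select`
#'   (`n`, optional), `permute` (`B`, optional extra EM options), `drugnet`
#'   (`edges`, `drug_targets`, `threshold`), `enrich` (`gmt`, optional
#'   `background`).
#' @return The manifest tibble, invisibly; also written to
#'   `manifest.tsv`.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% stop("config needs output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    writeLines(line, log_con)
    message(line)
  }

  manifest <- list()
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, enabled, fun) {
    if (!enabled) {
      log_msg("stage ", name, ": skipped")
      manifest[[name]] <<- tibble::tibble(stage = name, status = "skipped",
                                          outputs = "", md5 = "", seconds = 0)
      return(invisible(NULL))
    }
    log_msg("stage ", name, ": start")
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) {
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    sums <- unname(tools::md5sum(outputs))
    manifest[[name]] <<- tibble::tibble(
      stage = name, status = "done",
      outputs = paste(basename(outputs), collapse = ";"),
      md5 = paste(sums, collapse = ";"), seconds = round(dt, 3)
    )
    log_msg("stage ", name, ": done in ", round(dt, 2), "s")
  }

  mod <- config$model %||% list()
  r <- mod$r %||% 2
  r_k <- unlist(mod$r_k %||% 2)

  # ---- stage 1: data (simulate or preprocess)
  run_stage("preprocess", TRUE, function() {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      cf <- if (identical(sc$preset, "luhmes")) {
        luhmes_config(p = sc$p %||% 500, seed = seed)
      } else {
        do.call(sim_config, c(sc[setdiff(names(sc), "preset")],
                              list(seed = seed)))
      }
      sim <- simulate_stack(cf)
      state$truth <- sim
      state$stack <- standardize_stack(sim$stack)
    } else {
      pp <- config$preprocess %||% stop("either simulate or preprocess block required")
      raw <- read_omics_datasets(unlist(pp$expr), pp$meta)
      state$stack <- preprocess_stack(raw, read_mapping_tsv(pp$map),
                                      reference = pp$reference,
                                      iqr = isTRUE(pp$iqr))
    }
    dir <- file.path(out_dir, "stack")
    write_stack_dir(state$stack, dir)
    list.files(dir, full.names = TRUE)
  })

  # ---- stage 2: model fit
  run_stage("fit", TRUE, function() {
    state$fit <- poplsda(state$stack, r = r, r_k = r_k,
                         max_iter = mod$max_iter %||% 1000,
                         tol = mod$tol %||% 1e-6,
                         n_starts = mod$n_starts %||% 5, seed = seed)
    fp <- file.path(out_dir, "fit.json")
    write_fit_json(state$fit, fp)
    sp <- file.path(out_dir, "scores.tsv")
    readr::write_tsv(augment.poplsda_fit(state$fit), sp)
    c(fp, sp)
  })

  # ---- stage 3: feature selection
  run_stage("select", TRUE, function() {
    n_sel <- (config$select %||% list())$n
    state$ranking <- select_top(rank_features(state$fit), n = n_sel)
    rp <- file.path(out_dir, "ranking.tsv")
    readr::write_tsv(state$ranking, rp)
    rp
  })

  # ---- stage 4: permutation inference
  pm <- config$permute
  run_stage("permute", !is.null(pm), function() {
    perm <- permutation_test(
      state$stack, B = pm$B %||% 400, seed = seed, r = r, r_k = r_k,
      n_select = pm$n_select %||% attr(state$ranking, "n_selected"),
      n_starts = pm$n_starts %||% 1, max_iter = pm$max_iter %||% 200,
      tol = pm$tol %||% 1e-5
    )
    state$perm <- perm
    fp <- file.path(out_dir, "perm.json")
    jsonlite::write_json(
      list(B = perm$B, accuracies = perm$accuracies,
           n_perfect = perm$n_perfect, p_value = perm$p_value,
           observed_accuracy = perm$observed_accuracy, seed = perm$seed),
      fp, auto_unbox = TRUE, digits = NA
    )
    fp
  })

  # ---- stage 5: drug-target network integration
  dn <- config$drugnet
  run_stage("drugnet", !is.null(dn) && !is.null(dn$edges), function() {
    net <- load_network(dn$edges, threshold = dn$threshold %||% 0.4)
    targets <- readr::read_tsv(dn$drug_targets, comment = "#",
                               show_col_types = FALSE)
    names(targets)[1:2] <- c("drug", "gene")
    expanded <- expand_targets(targets, net)
    counts <- count_links(expanded, selected_features(state$ranking))
    gp <- file.path(out_dir, "gene_halos.tsv")
    dp <- file.path(out_dir, "drug_interactors.tsv")
    readr::write_tsv(counts$genes, gp)
    readr::write_tsv(counts$drugs, dp)
    c(gp, dp)
  })

  # ---- stage 6: enrichment
  en <- config$enrich
  run_stage("enrich", !is.null(en) && !is.null(en$gmt), function() {
    terms <- read_gmt(en$gmt)
    background <- if (!is.null(en$background)) {
      readLines(en$background)
    } else {
      state$stack$feature_ids
    }
    tbl <- fisher_enrichment(selected_features(state$ranking), terms,
                             background)
    ep <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(tbl, ep)
    ep
  })

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  log_msg("workflow complete: ", sum(manifest$status == "done"),
          " stage(s) done, ", sum(manifest$status == "skipped"), " skipped")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
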