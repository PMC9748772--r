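#' Select a representative painting from sampled histories
#'
#' Returns the sampled history whose internal-node states have the highest
#' summed log marginal posterior (a maximum-a-posteriori-flavoured choice
#' among the sampled maps), used as the default single painting for the
#' regime-dependent continuous models.
#'
#' @param hs a `historySet`.
#' @param summary its `transitionSummary` (computed if missing).
#' @return a painted phylogeny (`simmap`).
#' @export
selectPainting <- function(hs, summary = NULL) {
  summary <- summary %||% summarizeHistories(hs)
  post <- summary$node_posterior
  nodes <- rownames(post)
  score <- vapply(hs$histories, function(h) {
    st <- h$node_states[nodes]
    sum(log(pmax(post[cbind(nodes, st)], 1e-12)))
  }, numeric(1))
  hs$histories[[which.max(score)]]$tree
}

defaultPipelineConfig <- function() {
  list(tree = NULL, traits = NULL, overrides = NULL, outdir = "results",
       seed = 1, prune = FALSE,
       stages = list(classify = TRUE, mk = TRUE, map = TRUE,
                     tiprates = TRUE, anova = TRUE, sse = TRUE,
                     cont = TRUE),
       n_maps = 100, nsim = 1000, mk_restarts = 10, sse_restarts = 8,
       cont_restarts = 3)
}

#' Run the full comparative pipeline
#'
#' Stage order: classify, Mk batteries (both state systems), stochastic
#' mapping + transition summary, DR tip rates, ANOVAs (DR and mass against
#' niche and diet), the seven-model diversification battery, and the
#' 14-model continuous battery. Each stage writes its CSV/JSON artifacts
#' under `outdir` and the run ends with a manifest (config echo, config
#' hash, per-stage seeds and wall times). One global seed derives per-stage
#' sub-streams, so stage reruns are independent; rerunning with the same
#' config and inputs reproduces all outputs.
#'
#' @param config a named list (see `vignette`), or path to a YAML file with
#'   the same structure. Unknown keys are rejected. `tree`/`traits` may be
#'   file paths or in-memory objects.
#' @return (invisibly) a list of stage results; artifacts under
#'   `config$outdir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  def <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (is.null(cfg$tree) || is.null(cfg$traits)) {
    stopf("config must supply `tree` and `traits`")
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ratchetphy",
                   version = as.character(utils::packageVersion("ratchetphy")),
                   r_version = R.version.string,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = cfg$seed, stages = list())
  cfg_echo <- cfg
  cfg_echo$tree <- if (is.character(cfg$tree)) cfg$tree else "<in-memory>"
  cfg_echo$traits <- if (is.character(cfg$traits)) cfg$traits else
    "<in-memory>"
  cfg_path <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # hash the analysis-relevant config (where outputs go is not part of it)
  hobj <- cfg_echo
  hobj$outdir <- NULL
  htmp <- tempfile(fileext = ".json")
  jsonlite::write_json(hobj, htmp, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(htmp))
  unlink(htmp)

  tree <- if (is.character(cfg$tree)) readNewick(file = cfg$tree) else
    cfg$tree
  traits <- if (is.character(cfg$traits)) readTraitTable(cfg$traits) else
    cfg$traits
  overrides <- NULL
  if (!is.null(cfg$overrides)) {
    od <- if (is.character(cfg$overrides)) readTraitTable(cfg$overrides)
      else cfg$overrides
    overrides <- setNames(od$niche4, od$species)
  }
  res <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    sd <- deriveSeed(cfg$seed, name)
    out <- tryCatch(fn(sd), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$outdir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      status = "done", seed = sd,
      wall_s = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }

  res$classify <- stage("classify", cfg$stages$classify, function(sd) {
    tab <- if ("raw_niche" %in% names(traits)) {
      classifyNiches(traits, overrides)
    } else traits
    rep <- validateAgainstTree(tab, tree, prune = cfg$prune)
    if (!rep$ok && !cfg$prune) {
      stopf("tree/trait label mismatch (%d + %d); set prune: true",
            length(rep$missing_in_table), length(rep$missing_in_tree))
    }
    if (cfg$prune) {
      tree <<- rep$tree
      tab <- rep$table
    }
    writeTraitTable(tab, file.path(cfg$outdir, "traits_classified.csv"))
    tab
  })
  tab <- res$classify %||% traits
  st2 <- setNames(tab$niche2, tab$species)
  st4 <- setNames(tab$niche4, tab$species)
  mass <- setNames(tab$mass_log10, tab$species)

  res$mk <- stage("mk", cfg$stages$mk, function(sd) {
    out <- list()
    for (sys in c("two-state", "four-state")) {
      st <- if (sys == "two-state") st2 else st4
      bat <- runMkBattery(tree, st, sys, restarts = cfg$mk_restarts,
                          seed = deriveSeed(sd, sys))
      writeComparison(bat$comparison,
                      file.path(cfg$outdir, sprintf("mk_%s.csv", sys)))
      jsonlite::write_json(
        lapply(bat$fits, function(f) list(Q = f$Q, logL = f$logL,
                                          K = f$K)),
        file.path(cfg$outdir, sprintf("mk_%s_fits.json", sys)),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      out[[sys]] <- bat
    }
    out
  })

  res$map <- stage("map", cfg$stages$map, function(sd) {
    if (is.null(res$mk)) stopf("mapping requires the mk stage")
    out <- list()
    for (sys in c("two-state", "four-state")) {
      bat <- res$mk[[sys]]
      best <- bat$fits[[bat$comparison$name[1]]]
      st <- if (sys == "two-state") st2 else st4
      hs <- sampleHistories(tree, st, best, n = cfg$n_maps,
                            seed = deriveSeed(sd, sys))
      sm <- summarizeHistories(hs)
      writeHistories(hs, sm, file.path(cfg$outdir, paste0("map_", sys)))
      out[[sys]] <- list(histories = hs, summary = sm,
                         painting = selectPainting(hs, sm))
    }
    out
  })

  res$tiprates <- stage("tiprates", cfg$stages$tiprates, function(sd) {
    dr <- drStatistic(tree)
    utils::write.csv(dr, file.path(cfg$outdir, "tiprates.csv"),
                     row.names = FALSE)
    dr
  })

  res$anova <- stage("anova", cfg$stages$anova, function(sd) {
    dr <- res$tiprates %||% drStatistic(tree)
    drv <- setNames(dr$DR, dr$species)
    tests <- list(
      dr_niche2 = list(g = st2, v = drv),
      dr_niche4 = list(g = st4, v = drv),
      dr_diet = list(g = setNames(tab$diet, tab$species), v = drv),
      mass_niche2 = list(g = st2, v = mass),
      mass_niche4 = list(g = st4, v = mass))
    out <- lapply(seq_along(tests), function(i) {
      phyloAnova(tree, tests[[i]]$g, tests[[i]]$v, nsim = cfg$nsim,
                 seed = deriveSeed(sd, i))
    })
    names(out) <- names(tests)
    jsonlite::write_json(
      lapply(out, function(a) list(F = a$F, p_standard = a$p_standard,
                                   p_phylo = a$p_phylo,
                                   eta_squared = a$eta_squared,
                                   pairwise_p_phylo = a$pairwise_p_phylo)),
      file.path(cfg$outdir, "anova.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
    out
  })

  res$sse <- stage("sse", cfg$stages$sse, function(sd) {
    bat <- runSseBattery(tree, st2, restarts = cfg$sse_restarts, seed = sd)
    writeComparison(bat$comparison, file.path(cfg$outdir, "sse.csv"))
    best <- bat$fits[[bat$comparison$name[1]]]
    jsonlite::write_json(
      list(best = best$model$name,
           net_diversification = as.list(best$net_div),
           lambda = as.list(best$params$lambda),
           mu = as.list(best$params$mu)),
      file.path(cfg$outdir, "sse_best.json"), auto_unbox = TRUE,
      digits = NA)
    bat
  })

  res$cont <- stage("cont", cfg$stages$cont, function(sd) {
    if (is.null(res$map)) stopf("continuous battery requires the map stage")
    paintings <- list("two-state" = res$map[["two-state"]]$painting,
                      "four-state" = res$map[["four-state"]]$painting)
    bat <- runContBattery(tree, paintings, mass,
                          restarts = cfg$cont_restarts, seed = sd)
    writeComparison(bat$comparison, file.path(cfg$outdir, "cont.csv"))
    jsonlite::write_json(
      lapply(bat$fits, function(f) list(
        theta = as.list(f$params$theta), alpha = as.list(f$params$alpha),
        sigma2 = as.list(f$params$sigma2),
        half_life = as.list(f$params$half_life %||% NULL))),
      file.path(cfg$outdir, "cont_fits.json"), auto_unbox = TRUE,
      digits = NA)
    bat
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
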