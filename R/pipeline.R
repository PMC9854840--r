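# Config-driven orchestration: TPS + pedigree in, heritability report out.

default_config_ <- function() {
  list(tps = NULL, pedigree = NULL, out_dir = NULL, scheme = NULL,
       n_pcs = 15L, slide = TRUE, pinv_rtol = 1e-10,
       reml = list(components = c("animal", "maternal", "paternal"),
                   max_iter = 2000L, tol_logl = 1e-8, tol_par = 1e-6,
                   accelerate = TRUE),
       dimorphism = list(enabled = TRUE, n_perm = 1000L, seed = 1L))
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration (or completes an in-memory list) against the
#' defaults: `tps`, `pedigree`, `out_dir`, optional `scheme` (YAML path;
#' default the built-in 40-landmark head scheme), `n_pcs` (default 15),
#' `slide`, `pinv_rtol`, `reml` settings (`components`, `max_iter`,
#' `tol_logl`, `tol_par`, `accelerate`) and `dimorphism` settings
#' (`enabled`, `n_perm`, `seed`).
#'
#' @param config Path to a YAML file, or a named list.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_config_()
  merged <- utils::modifyList(def, config)
  if (is.null(merged$tps) || is.null(merged$pedigree) ||
      is.null(merged$out_dir))
    stop("config must provide tps, pedigree and out_dir", call. = FALSE)
  if (merged$n_pcs < 1L) stop("n_pcs must be >= 1", call. = FALSE)
  if (merged$dimorphism$n_perm < 1L) stop("n_perm must be >= 1",
                                          call. = FALSE)
  merged
}

stage_ <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

write_matrix_ <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(trait = rownames(m) %||% paste0("PC", seq_len(nrow(m))), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full shape-heritability pipeline
#'
#' Executes the analysis sequence on files named in the configuration:
#' read TPS and pedigree, Generalized Procrustes Analysis (with
#' semilandmark sliding if configured), symmetric-component extraction,
#' shape PCA, optional sexual-dimorphism permutation tests on shape and
#' log centroid size (adults and offspring separately; the outcome does
#' not gate the pipeline -- sexes are pooled for the heritability fit
#' regardless), multivariate REML, and the heritability summary. All
#' intermediate tables, the report (JSON), the REML fit log, and a
#' manifest are written to `out_dir`.
#'
#' @param config Path to a YAML configuration or a named list; see
#'   [pipeline_config()].
#' @return Object of class `pipeline_result` (invisibly): all stage
#'   outputs plus file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  scheme <- stage_("scheme", {
    if (is.null(cfg$scheme)) viper_head_scheme()
    else read_landmark_scheme(cfg$scheme)
  })
  configs <- stage_("read_tps", read_tps(cfg$tps, scheme))
  ped <- stage_("read_pedigree", read_pedigree(cfg$pedigree))
  note("read %d configurations, pedigree of %d", length(configs), nrow(ped))

  aligned <- stage_("gpa", gpa(configs, scheme, slide = isTRUE(cfg$slide)))
  note("GPA done (%d alignment iterations logged)",
       length(attr(aligned, "rss")))
  symm <- stage_("symmetric_component", symmetric_component(aligned, scheme))
  space <- stage_("shape_pca", shape_pca(symm, n_retained = cfg$n_pcs))
  note("PCA: %d positive eigenvalues, %d retained (%.2f%% of variance)",
       space$n_positive, space$n_retained,
       100 * space$cumulative[space$n_retained])

  dimorphism <- NULL
  if (isTRUE(cfg$dimorphism$enabled) && "sex" %in% names(ped)) {
    dimorphism <- stage_("dimorphism", {
      pos <- match(symm$ids, ped$id)
      sex <- ped$sex[pos]
      adult <- ped$founder[pos]
      res <- list()
      for (grp in c("adults", "offspring")) {
        keep <- !is.na(sex) & (if (grp == "adults") adult else !adult)
        if (sum(keep) >= 4L && all(table(factor(sex[keep])) >= 2L) &&
            length(unique(sex[keep])) == 2L) {
          res[[paste0(grp, "_shape")]] <- procrustes_anova(
            space$scores[keep, , drop = FALSE], sex[keep],
            n_perm = cfg$dimorphism$n_perm, seed = cfg$dimorphism$seed)
          res[[paste0(grp, "_logCS")]] <- procrustes_anova(
            log(symm$centroid_sizes[keep]), sex[keep],
            n_perm = cfg$dimorphism$n_perm, seed = cfg$dimorphism$seed)
        }
      }
      res
    })
    for (nmx in names(dimorphism))
      note("dimorphism %s: F = %.3f, p = %.4f", nmx,
           dimorphism[[nmx]]$statistic, dimorphism[[nmx]]$p_value)
  }

  amd <- stage_("animal_model_data",
                animal_model_data(space$scores, log(symm$centroid_sizes),
                                  symm$ids, ped))
  vc <- stage_("reml_fit", do.call(reml_fit, c(
    list(data = amd, ped = ped),
    cfg$reml[intersect(names(cfg$reml),
                       c("components", "max_iter", "tol_logl", "tol_par",
                         "accelerate", "ai_start"))])))
  note("REML: logL = %.6f after %d iterations (%s)", vc$logL, vc$n_iter,
       if (vc$converged) "converged" else "NOT converged")
  herit <- stage_("heritability_summary",
                  heritability_summary(vc, rtol = cfg$pinv_rtol))

  # --- materialize stage outputs -------------------------------------
  paths <- list()
  wr <- function(name, fun) {
    paths[[name]] <<- file.path(cfg$out_dir, name)
    fun(paths[[name]])
  }
  shape_df <- function(al) data.frame(id = al$ids, cs = al$centroid_sizes,
                                      al$shapes, check.names = FALSE)
  wr("aligned_shapes.csv", function(p)
    utils::write.csv(shape_df(aligned), p, row.names = FALSE))
  wr("symmetric_shapes.csv", function(p)
    utils::write.csv(shape_df(symm), p, row.names = FALSE))
  wr("pca_summary.csv", function(p)
    utils::write.csv(summary(space), p, row.names = FALSE))
  wr("pca_scores.csv", function(p)
    utils::write.csv(data.frame(id = space$ids, space$scores), p,
                     row.names = FALSE))
  for (comp in c("G", "Mat", "Pat", "R", "P"))
    wr(sprintf("vc_%s.csv", comp),
       local({ m <- vc[[comp]]; function(p) write_matrix_(m, p) }))
  wr("fit_log.txt", function(p)
    writeLines(c(log_lines,
                 sprintf("iter %d logL %.10f %s", seq_along(vc$logL_path),
                         vc$logL_path,
                         c(vc$steps, "")[seq_along(vc$logL_path)])), p))
  report <- list(
    proportions = as.list(herit$proportions),
    h2_max = herit$h2_max,
    mat_max = herit$mat_max,
    GPm_eigenvalues = herit$GPm_eigenvalues,
    GPm_cumulative = herit$GPm_cumulative,
    MatPm_eigenvalues = herit$MatPm_eigenvalues,
    MatPm_cumulative = herit$MatPm_cumulative,
    angles_deg = as.list(herit$angles_deg),
    component_eigenvalues = herit$component_eigenvalues,
    reml = list(logL = vc$logL, n_iter = vc$n_iter,
                converged = vc$converged),
    dimorphism = lapply(dimorphism, function(d)
      list(F = d$statistic, Z = d$effect_size, p = d$p_value,
           n_perm = d$n_permutations)))
  wr("heritability_report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  manifest <- list(
    config = cfg,
    package = as.character(utils::packageVersion("morphherit")),
    r_version = R.version.string,
    started = format(t0), finished = format(Sys.time()),
    input_md5 = as.list(tools::md5sum(c(cfg$tps, cfg$pedigree))),
    output_md5 = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(config = cfg, aligned = aligned, symmetric = symm,
                 pca = space, dimorphism = dimorphism, vc = vc,
                 heritability = herit, report = report, paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("morphherit pipeline result\n")
  print(x$heritability)
  invisible(x)
}
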