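#' Assemble an analysis configuration
#'
#' Collects the inputs of [run_full_analysis()]: data (alignment + labelled
#' tree), the paralog group definitions, the models to fit and compare, the
#' sliding-window settings, and the clock calibration. Any field can also be
#' supplied via a JSON file read with [read_analysis_config()].
#'
#' @param alignment a \code{codon_alignment} or FASTA path.
#' @param tree a \code{labeled_tree}, or a Newick path (then
#'   \code{labels} gives the branch-class TSV).
#' @param labels optional branch-class TSV path (with a Newick \code{tree}).
#' @param groups list with character vectors \code{g1}, \code{g5} (sequence
#'   ids of the two paralog clades) and a single \code{outgroup} id.
#' @param branch_models branch model names to fit (see
#'   [branch_model_spec()]); \code{"M0"} is always fitted first.
#' @param branch_lrt_pairs list of c(alt, null) name pairs to test.
#' @param site_models site model names to fit (see [site_model_spec()]).
#' @param site_lrt_pairs list of c(alt, null) pairs among the site models.
#' @param branch_site_foregrounds named list of branch-class sets, each
#'   fitted with branch-site models A and B (A compared against M1, B
#'   against the K=2 discrete model).
#' @param window list(window_nt, step_nt) for the sliding-window profiles.
#' @param calibration either NULL (skip dating), or
#'   list(T_calibration, dS_ortholog, dS_paralog) with explicit distances,
#'   or list(T_calibration, ortholog_pair = c(id, id),
#'   paralog_pair = c(id, id)) to compute the dS inputs from the alignment.
#' @param out_dir output directory for the report bundle.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the config is used to regenerate
#'   simulated input).
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(alignment, tree, labels = NULL, groups,
                            branch_models = c("M0", "M2r", "M3r", "M4r",
                                              "M5r"),
                            branch_lrt_pairs = list(
                              c("M2r", "M0"), c("M3r", "M2r"),
                              c("M4r", "M3r"), c("M5r", "M4r")),
                            site_models = c("M0", "M1", "M2", "M3", "M7",
                                            "M8"),
                            site_lrt_pairs = list(
                              c("M3", "M0"), c("M2", "M1"), c("M8", "M7")),
                            branch_site_foregrounds = list(
                              g1 = c("stem_g1", "g1"),
                              g5 = c("stem_g5", "g5")),
                            window = list(window_nt = 30L, step_nt = 9L),
                            calibration = NULL,
                            out_dir = "paralogsel_run", seed = 1L) {
  stopifnot(is.list(groups), all(c("g1", "g5") %in% names(groups)))
  structure(list(alignment = alignment, tree = tree, labels = labels,
                 groups = groups, branch_models = branch_models,
                 branch_lrt_pairs = branch_lrt_pairs,
                 site_models = site_models, site_lrt_pairs = site_lrt_pairs,
                 branch_site_foregrounds = branch_site_foregrounds,
                 window = window, calibration = calibration,
                 out_dir = out_dir, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path JSON file with fields as in [analysis_config()]; file paths
#'   in \code{alignment} / \code{tree} / \code{labels} are resolved
#'   relative to the JSON file's directory.
#' @return an \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p) &&
                         file.exists(file.path(base, p)))
    file.path(base, p) else p
  j$alignment <- rel(j$alignment)
  j$tree <- rel(j$tree)
  if (!is.null(j$labels)) j$labels <- rel(j$labels)
  if (!is.null(j$branch_lrt_pairs) && is.matrix(j$branch_lrt_pairs))
    j$branch_lrt_pairs <- split(j$branch_lrt_pairs,
                                row(j$branch_lrt_pairs)[, 1])
  if (!is.null(j$site_lrt_pairs) && is.matrix(j$site_lrt_pairs))
    j$site_lrt_pairs <- split(j$site_lrt_pairs, row(j$site_lrt_pairs)[, 1])
  do.call(analysis_config, j)
}

#' Run the full duplicate-gene selection analysis
#'
#' End-to-end workflow over one codon alignment and labelled gene tree:
#' (a) branch-model table with the LRT cascade; (b) site and branch-site
#' model table with their LRTs and naive-empirical-Bayes site flags;
#' (c) relative-rate-test table over matched paralog pairs; (d) sliding
#' window profiles (within each paralog group and between groups);
#' (e) composition and codon-usage table with the group contrasts;
#' (f) clock dating; plus a machine-readable manifest. Any stage failure
#' aborts with a stage-named error after writing a \code{FAILED} marker;
#' artifacts of completed stages are retained.
#'
#' @param config an \code{analysis_config} (or path to its JSON).
#' @param quiet suppress per-stage progress lines.
#' @return invisibly, a list with every table and fit object, the paths of
#'   the written artifacts, and the manifest.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message("[paralogsel] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage '", name, "': ",
                        conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(paths = character(0))
  add_tsv <- function(d, file) {
    p <- file.path(out, file)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    res$paths <<- c(res$paths, p)
    p
  }

  # -- load & validate ------------------------------------------------------
  aln <- tree <- NULL
  stage("validate", {
    aln <- if (inherits(config$alignment, "codon_alignment"))
      config$alignment else read_codon_fasta(config$alignment)
    tree <- if (inherits(config$tree, "labeled_tree")) config$tree
      else read_labeled_tree(config$tree, config$labels)
    if (!all(tree$phy$tip.label %in% aln$names))
      stop("tree taxa missing from the alignment")
    g <- config$groups
    if (!all(c(g$g1, g$g5, g$outgroup) %in% aln$names))
      stop("group ids missing from the alignment")
  })
  g1 <- config$groups$g1
  g5 <- config$groups$g5
  outg <- config$groups$outgroup

  # -- composition & codon usage -------------------------------------------
  stage("composition", {
    comp <- gc_content(aln)
    usage <- enc_table(aln)
    comp <- merge(comp[, c("seq_id", "gc_total", "gc1", "gc2", "gc3")],
                  usage[, c("seq_id", "enc")], by = "seq_id", sort = FALSE)
    comp$group <- ifelse(comp$seq_id %in% g1, "g1",
                         ifelse(comp$seq_id %in% g5, "g5", "other"))
    in1 <- comp$group == "g1"; in5 <- comp$group == "g5"
    cmp_gc3 <- compare_groups(comp$gc3[in1], comp$gc3[in5])
    cmp_enc <- compare_groups(comp$enc[in1], comp$enc[in5])
    contrasts <- data.frame(
      statistic = c("gc3", "enc"),
      mean_g1 = c(cmp_gc3$mean_a, cmp_enc$mean_a),
      mean_g5 = c(cmp_gc3$mean_b, cmp_enc$mean_b),
      t = c(cmp_gc3$t_stat, cmp_enc$t_stat),
      p_value = c(cmp_gc3$p_value, cmp_enc$p_value),
      stars = significance_stars(c(cmp_gc3$p_value, cmp_enc$p_value)))
    add_tsv(comp, "composition.tsv")
    add_tsv(contrasts, "composition_contrasts.tsv")
    res$composition <- comp
    res$composition_contrasts <- contrasts
  })

  # -- counting-based divergence & windows ---------------------------------
  stage("divergence", {
    div1 <- mean_divergence(aln, g1)
    div5 <- mean_divergence(aln, g5)
    divergence <- data.frame(
      group = c("g1", "g5"),
      mean_dN = c(div1$mean_dN, div5$mean_dN),
      mean_dS = c(div1$mean_dS, div5$mean_dS),
      overall_omega = c(div1$overall_omega, div5$overall_omega),
      n_pairs = c(div1$n_pairs, div5$n_pairs))
    add_tsv(divergence, "divergence.tsv")
    res$divergence <- divergence

    wp <- function(ids_a, ids_b = NULL) {
      prs <- if (is.null(ids_b)) t(utils::combn(ids_a, 2))
             else as.matrix(expand.grid(ids_a, ids_b,
                                        stringsAsFactors = FALSE))
      sliding_window(aln, prs, config$window$window_nt,
                     config$window$step_nt)
    }
    res$windows <- list(g1 = wp(g1), g5 = wp(g5), between = wp(g1, g5))
    add_tsv(as.data.frame(res$windows$g1), "window_g1.tsv")
    add_tsv(as.data.frame(res$windows$g5), "window_g5.tsv")
    add_tsv(as.data.frame(res$windows$between), "window_between.tsv")
  })

  # -- relative rate tests --------------------------------------------------
  stage("relative_rate_tests", {
    n <- min(length(g1), length(g5))
    rows <- lapply(seq_len(n), function(i) {
      r <- tajima_rrt(aln$sequences[match(g1[i], aln$names)],
                      aln$sequences[match(g5[i], aln$names)],
                      aln$sequences[match(outg, aln$names)])
      data.frame(seq_g1 = g1[i], seq_g5 = g5[i], outgroup = outg,
                 m1 = r$m1, m2 = r$m2, ratio_g1_g5 = r$ratio,
                 chi2 = r$chi2, p_value = r$p_value,
                 stars = significance_stars(r$p_value))
    })
    rrt_tab <- do.call(rbind, rows)
    add_tsv(rrt_tab, "rrt.tsv")
    res$rrt <- rrt_tab
  })

  # -- branch models --------------------------------------------------------
  fits <- list()
  stage("branch_models", {
    fits$M0 <- fit_codon_model(aln, tree, branch_model_spec("M0"))
    kap <- fits$M0$estimates$kappa
    tr0 <- fits$M0$tree
    for (bm in setdiff(config$branch_models, "M0"))
      fits[[bm]] <- fit_codon_model(aln, tr0, branch_model_spec(bm),
                                    kappa = kap, branch_lengths = "fixed")
    rows <- lapply(config$branch_models, function(bm) {
      f <- fits[[bm]]
      om <- f$omega_kc[1, ]
      om_txt <- paste(sprintf("%s=%s", names(om),
                              ifelse(om >= 990, "Inf",
                                     formatC(om, digits = 4,
                                             format = "fg"))),
                      collapse = " ")
      data.frame(model = bm, p = f$n_params, lnL = round(f$lnL, 2),
                 omega = om_txt, converged = f$converged)
    })
    tab <- do.call(rbind, rows)
    lrt_rows <- lapply(config$branch_lrt_pairs, function(pr) {
      r <- lrt(fits[[pr[2]]], fits[[pr[1]]])
      data.frame(alt = pr[1], null = pr[2], stat = round(r$stat, 2),
                 df = r$df, p_value = r$p_value,
                 stars = significance_stars(r$p_value))
    })
    lrt_tab <- do.call(rbind, lrt_rows)
    add_tsv(tab, "branch_models.tsv")
    add_tsv(lrt_tab, "branch_lrt.tsv")
    res$branch_models <- tab
    res$branch_lrt <- lrt_tab
  })
  kap <- fits$M0$estimates$kappa
  tr0 <- fits$M0$tree

  # -- site & branch-site models -------------------------------------------
  stage("site_models", {
    sfits <- list()
    for (sm in config$site_models)
      sfits[[sm]] <- fit_codon_model(aln, tr0, site_model_spec(sm),
                                     kappa = kap, branch_lengths = "fixed")
    sfits[["M3K2"]] <- fit_codon_model(aln, tr0,
                                       site_model_spec("M3", n_classes = 2),
                                       kappa = kap,
                                       branch_lengths = "fixed")
    for (fg in names(config$branch_site_foregrounds)) {
      cls <- config$branch_site_foregrounds[[fg]]
      sfits[[paste0("bsA_", fg)]] <- fit_codon_model(
        aln, tr0, site_model_spec("bsA", foreground = cls),
        kappa = kap, branch_lengths = "fixed")
      sfits[[paste0("bsB_", fg)]] <- fit_codon_model(
        aln, tr0, site_model_spec("bsB", foreground = cls),
        kappa = kap, branch_lengths = "fixed")
    }
    pairs <- config$site_lrt_pairs
    for (fg in names(config$branch_site_foregrounds)) {
      pairs <- c(pairs, list(c(paste0("bsA_", fg), "M1"),
                             c(paste0("bsB_", fg), "M3K2")))
    }
    rows <- lapply(names(sfits), function(nm) {
      f <- sfits[[nm]]
      flags <- ""
      if (length(f$weights) > 1L && any(f$omega_kc > 1 + 1e-9)) {
        sp <- site_posteriors(f)
        if (nrow(sp$flagged_sites))
          flags <- paste(sprintf("%d%s", sp$flagged_sites$site,
                                 sp$flagged_sites$residue), collapse = ",")
      }
      data.frame(model = nm, p = f$n_params, lnL = round(f$lnL, 2),
                 proportions = paste(round(f$weights, 3), collapse = ","),
                 omegas = paste(ifelse(f$omega_kc[, 1] >= 990, "Inf",
                                       round(f$omega_kc[, 1], 3)),
                                collapse = ","),
                 positive_sites = flags, converged = f$converged)
    })
    tab <- do.call(rbind, rows)
    lrt_rows <- lapply(pairs, function(pr) {
      r <- suppressWarnings(lrt(sfits[[pr[2]]], sfits[[pr[1]]]))
      data.frame(alt = pr[1], null = pr[2], stat = round(r$stat, 2),
                 df = r$df, p_value = r$p_value, negative = r$negative,
                 stars = significance_stars(r$p_value))
    })
    lrt_tab <- do.call(rbind, lrt_rows)
    add_tsv(tab, "site_models.tsv")
    add_tsv(lrt_tab, "site_lrt.tsv")
    res$site_models <- tab
    res$site_lrt <- lrt_tab
    res$site_fits <- sfits
  })
  res$branch_fits <- fits

  # -- clock dating ---------------------------------------------------------
  if (!is.null(config$calibration)) stage("clock_dating", {
    cal <- config$calibration
    if (is.null(cal$dS_ortholog)) {
      d_or <- ng86_pair(
        aln$sequences[match(cal$ortholog_pair[1], aln$names)],
        aln$sequences[match(cal$ortholog_pair[2], aln$names)])
      d_pa <- ng86_pair(
        aln$sequences[match(cal$paralog_pair[1], aln$names)],
        aln$sequences[match(cal$paralog_pair[2], aln$names)])
      cal$dS_ortholog <- d_or$dS
      cal$dS_paralog <- d_pa$dS
    }
    ce <- clock_date(cal$dS_ortholog, cal$dS_paralog, cal$T_calibration)
    p <- file.path(out, "clock.json")
    jsonlite::write_json(unclass(ce), p, auto_unbox = TRUE, digits = NA)
    res$paths <- c(res$paths, p)
    res$clock <- ce
  })

  # -- manifest -------------------------------------------------------------
  stage("manifest", {
    manifest <- list(
      package = "paralogsel",
      version = as.character(utils::packageVersion("paralogsel")),
      n_sequences = length(aln$names), n_codons = aln$n_codons,
      seed = config$seed,
      branch_models = config$branch_models,
      site_models = config$site_models,
      elapsed_sec = as.numeric(difftime(Sys.time(), t_start,
                                        units = "secs")),
      artifacts = c(basename(res$paths), "manifest.json"))
    p <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    res$paths <- c(res$paths, p)
    res$manifest <- manifest
  })
  say("done: ", length(res$paths), " artifacts in ", out)
  invisible(res)
}
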