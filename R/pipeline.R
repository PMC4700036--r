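## Report pipeline: one entry point running the full analysis from a
## hand-editable YAML config and emitting a JSON report plus TSV tables.

#' Regenerate the spacing-frequency table
#'
#' One row per free-cell count `n = 1..max_n`: the pooled Monte Carlo
#' frequency, the equal-weight theoretical (permutation) frequency, its
#' exact fraction, and the dynamics-exact expectation the Monte Carlo
#' converges to.
#'
#' @param max_n largest row length (guarded as in
#'   [enumerate_permutations()]).
#' @param mc_reps Monte Carlo replicates per row length.
#' @param seed RNG seed.
#' @return data.frame with columns `n`, `empirical`, `theoretical`,
#'   `fraction`, `dynamics_exact`.
#' @export
regenerate_table1 <- function(max_n = 10L, mc_reps = 1000L, seed = 1L) {
  rows <- lapply(seq_len(max_n), function(n) {
    emp <- monte_carlo_frequency(n, mc_reps, seed = seed + n)
    thy <- enumerate_permutations(n)
    dyn <- dynamics_exact_frequency(n)
    data.frame(n = n,
               empirical = emp$frequency,
               theoretical = thy$frequency,
               fraction = sprintf("%d/%d", thy$favorable, thy$total),
               dynamics_exact = dyn$frequency)
  })
  do.call(rbind, rows)
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis from a config file
#'
#' The YAML config lists the stages to run:
#'
#' ```yaml
#' seed: 1
#' rindex:
#'   - file: veins.csv
#'     dialect: transect
#'     topology: ring
#'     length: 400
#' table1:
#'   max_n: 6
#'   mc_reps: 500
#' leafpdf:
#'   d0: 10
#'   a: 1.07177
#'   T: 10
#'   f0: 0.1145
#'   m: 11.41
#'   smooth_p: 0.5
#' cellspace:
#'   n_free: 100
#'   n_reps: 200
#' ```
#'
#' Every stage is deterministic given the config (all randomness flows from
#' `seed`). Paths in the config are resolved relative to the config file.
#'
#' @param config path to a YAML config.
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus TSV tables.
#' @return An `"analysis_report"` list with elements `rindex`, `table1`,
#'   `leafpdf`, `cellspace` (as configured) and `provenance`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(config), error = function(e) {
    stop("[config] cannot parse: ", conditionMessage(e), call. = FALSE)
  })
  known <- c("seed", "rindex", "table1", "leafpdf", "cellspace")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("[config] unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  report <- list()

  if (!is.null(cfg$rindex)) {
    .stage_msg("rindex", "%d input(s)", length(cfg$rindex))
    report$rindex <- lapply(cfg$rindex, function(item) {
      path <- item$file
      if (!is.null(path) && !file.exists(path)) {
        path2 <- file.path(dirname(config), path)
        if (file.exists(path2)) path <- path2
        else stop("[rindex] missing input file: ", item$file, call. = FALSE)
      }
      dialect <- if (is.null(item$dialect)) "transect" else item$dialect
      obj <- read_pattern(path, dialect = dialect,
                          topology = if (is.null(item$topology)) "line"
                                     else item$topology,
                          length = item$length, area = item$area)
      res <- if (inherits(obj, "transect")) r_index_from_transect(obj)
             else r_index_from_pattern(obj)
      list(file = basename(path), r_value = res$r_value,
           mean_nn = res$mean_nn, density = res$density, dims = res$dims,
           n_points = res$n_points, label = classify_order(res))
    })
  }

  if (!is.null(cfg$table1)) {
    .stage_msg("table1", "n = 1..%d", cfg$table1$max_n)
    report$table1 <- regenerate_table1(
      max_n = if (is.null(cfg$table1$max_n)) 10L else cfg$table1$max_n,
      mc_reps = if (is.null(cfg$table1$mc_reps)) 1000L else cfg$table1$mc_reps,
      seed = seed)
  }

  if (!is.null(cfg$leafpdf)) {
    lp <- cfg$leafpdf
    .stage_msg("leafpdf", "T = %s", lp$T)
    gp <- growth_params(d0 = lp$d0 %||% 10, a = lp$a %||% 1.07177,
                        T = lp$T %||% 10, f0 = lp$f0 %||% 0.1145,
                        m = lp$m %||% 1)
    simple <- skijump_pdf(gp)
    smooth <- binomial_smooth(simple, p = lp$smooth_p %||% 0.5)
    report$leafpdf <- list(params = unclass(gp),
                           support = simple$support,
                           mass_simple = simple$mass,
                           mass_smoothed = smooth$mass)
    if (!is.null(lp$data)) {
      path <- lp$data
      if (!file.exists(path)) path <- file.path(dirname(config), lp$data)
      gaps <- utils::read.table(path, header = TRUE,
                                sep = if (grepl("\\.tsv$", path)) "\t" else ",")
      fit <- fit_distribution(gaps[[ncol(gaps)]], simple)
      report$leafpdf$fit <- list(discrepancy = fit$discrepancy,
                                 max_abs = fit$max_abs, n = fit$n)
    }
  }

  if (!is.null(cfg$cellspace)) {
    cs <- cfg$cellspace
    .stage_msg("cellspace", "n_free = %s", cs$n_free)
    mc <- monte_carlo_frequency(cs$n_free %||% 100,
                                cs$n_reps %||% 200, seed = seed)
    report$cellspace <- list(n_free = cs$n_free %||% 100,
                             n_reps = cs$n_reps %||% 200,
                             one_celled = mc$one_celled,
                             two_celled = mc$two_celled,
                             frequency = mc$frequency)
  }

  report$provenance <- list(
    config = basename(config),
    config_md5 = unname(tools::md5sum(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("tactostele")),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "analysis_report"
  validate_report(report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(report$table1)) {
      utils::write.table(report$table1, file.path(out_dir, "table1.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(report$leafpdf)) {
      utils::write.table(
        data.frame(distance = report$leafpdf$support,
                   mass_simple = report$leafpdf$mass_simple,
                   mass_smoothed = report$leafpdf$mass_smoothed),
        file.path(out_dir, "leafpdf.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  if (!is.null(x$rindex)) {
    for (r in x$rindex) {
      cat(sprintf("  rindex %s: R = %.3f (%s)\n", r$file, r$r_value, r$label))
    }
  }
  if (!is.null(x$table1)) {
    cat(sprintf("  table1: n = 1..%d\n", max(x$table1$n)))
  }
  if (!is.null(x$leafpdf)) cat("  leafpdf: model pdf computed\n")
  if (!is.null(x$cellspace)) {
    cat(sprintf("  cellspace: frequency %.4f\n", x$cellspace$frequency))
  }
  cat(sprintf("  seed %d, version %s\n", x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

#' Structural validation of an analysis report
#'
#' Checks the report against the schema shipped in
#' `inst/schema/analysis-report.json`: required provenance fields, and the
#' shape of each optional stage block.
#'
#' @param report an `"analysis_report"`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_report <- function(report) {
  prov <- report$provenance
  need <- c("config", "config_md5", "seed", "package_version", "timestamp")
  miss <- setdiff(need, names(prov))
  if (length(miss)) {
    stop("report provenance incomplete: missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(report$rindex)) {
    ok <- vapply(report$rindex, function(r) {
      all(c("r_value", "mean_nn", "density", "dims", "n_points", "label")
          %in% names(r)) && is.numeric(r$r_value)
    }, logical(1))
    if (!all(ok)) stop("malformed rindex block", call. = FALSE)
  }
  if (!is.null(report$table1) &&
      !all(c("n", "empirical", "theoretical", "fraction") %in%
           names(report$table1))) {
    stop("malformed table1 block", call. = FALSE)
  }
  if (!is.null(report$cellspace) &&
      !is.numeric(report$cellspace$frequency)) {
    stop("malformed cellspace block", call. = FALSE)
  }
  invisible(TRUE)
}
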