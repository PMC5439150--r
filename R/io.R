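sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a phenotype table from delimited text
#'
#' Expects a wide layout: one row per animal-time with columns `animal`,
#' `time`, one column per trait, plus any covariate/group columns.  Missing
#' trait cells (empty or the missing token) are dropped from the long
#' output with a message reporting the counts.
#'
#' @param path File path.
#' @param traits Character vector naming the trait columns.
#' @param missing Missing-value token in addition to empty cells (default
#'   `"NA"`).
#' @param delim Field delimiter (`NULL` = guess comma/tab from the header).
#' @return Long-format tibble (animal, time, trait, value, covariates).
#' @export
read_phenotypes <- function(path, traits, missing = "NA", delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, na = c("", missing),
                          show_col_types = FALSE)
  need <- c("animal", "time", traits)
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    abort(sprintf("Phenotype file lacks column(s): %s", paste(absent, collapse = ", ")))
  }
  dup <- duplicated(df[, c("animal", "time")])
  if (any(dup)) {
    abort(sprintf("Duplicated (animal, time) row in phenotype file (data line %d).",
                  which(dup)[1]))
  }
  df$animal <- as.character(df$animal)
  long <- tidyr::pivot_longer(df, dplyr::all_of(traits), names_to = "trait",
                              values_to = "value")
  n_miss <- sum(is.na(long$value))
  if (n_miss > 0) {
    message(sprintf("Dropped %d missing trait cell(s); %d record(s) loaded.",
                    n_miss, sum(!is.na(long$value))))
  }
  dplyr::filter(long, !is.na(.data$value))
}

#' Write a long-format phenotype table as wide delimited text
#'
#' Inverse of [read_phenotypes()]: trait records are spread into one column
#' per trait (empty cells for missing trait-time combinations).
#'
#' @param data Long-format tibble (animal, time, trait, value, covariates).
#' @param path Output file.
#' @param delim Field delimiter.
#' @return Invisibly `path`.
#' @export
write_phenotypes <- function(data, path, delim = ",") {
  wide <- tidyr::pivot_wider(data, names_from = "trait", values_from = "value")
  readr::write_delim(wide, path, delim = delim, na = "NA")
  invisible(path)
}

# ---- model-spec config serialization ---------------------------------------

effect_to_list <- function(eff) {
  list(
    within = lapply(eff$within, function(w)
      paste0(c(w$order, w$ante_degrees, w$innov_degree), collapse = "")),
    crosses = lapply(eff$crosses, function(cr) list(
      from = cr$from, to = cr$to, start_lag = cr$start_lag,
      end_lag = cr$end_lag, degrees = as.list(cr$degrees)
    )),
    initial_correlation = eff$initial_correlation
  )
}

effect_from_list <- function(x) {
  sad_effect(
    within = lapply(x$within, as.character),
    crosses = lapply(x$crosses %||% list(), function(cr)
      sad_cross(cr$from, cr$to, cr$start_lag, cr$end_lag,
                degrees = unlist(cr$degrees))),
    initial_correlation = isTRUE(x$initial_correlation)
  )
}

#' Serialize a model specification to a YAML config file
#'
#' The round trip `spec_from_config(spec_to_config(spec, path))` is
#' lossless.  Random-regression specifications are supported through the
#' `family` field.
#'
#' @param spec A [sad_model()] or [rr_model()] specification.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
spec_to_config <- function(spec, path) {
  if (inherits(spec, "rr_model_spec")) {
    cfg <- list(
      family = "RR",
      traits = as.list(spec$traits),
      times = as.list(spec$times),
      genetic_degree = as.list(spec$genetic_degree),
      permanent_degree = as.list(spec$permanent_degree),
      residual_cor = spec$residual_cor,
      fixed = lapply(spec$fixed, function(f) paste(deparse(f), collapse = " ")),
      group = spec$group
    )
  } else {
    cfg <- list(
      family = "SAD",
      traits = as.list(spec$traits),
      times = as.list(spec$times),
      genetic = effect_to_list(spec$genetic),
      permanent = effect_to_list(spec$permanent),
      fixed = lapply(spec$fixed, function(f) paste(deparse(f), collapse = " ")),
      group = spec$group
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#' @param path Config file written by [spec_to_config()] (or by hand in the
#'   same layout).
#' @return A [sad_model()] or [rr_model()] specification.
#' @export
spec_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  traits <- unlist(cfg$traits)
  fixed <- if (!is.null(cfg$fixed)) {
    lapply(cfg$fixed, function(s) as.formula(s, env = globalenv()))
  } else {
    NULL
  }
  if (identical(cfg$family, "RR")) {
    return(rr_model(
      traits = traits, times = unlist(cfg$times),
      genetic_degree = unlist(cfg$genetic_degree),
      permanent_degree = unlist(cfg$permanent_degree),
      residual_cor = isTRUE(cfg$residual_cor),
      fixed = fixed, group = cfg$group
    ))
  }
  sad_model(
    traits = traits, times = unlist(cfg$times),
    genetic = effect_from_list(cfg$genetic),
    permanent = effect_from_list(cfg$permanent),
    fixed = fixed, group = cfg$group
  )
}

# ---- run manifest -----------------------------------------------------------

write_manifest <- function(out_dir, inputs = character(), seed = NULL,
                           extra = list()) {
  manifest <- c(list(
    package = "sadmix",
    version = as.character(utils::packageVersion("sadmix")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = seed,
    inputs = lapply(inputs, function(f) list(
      path = f, md5 = unname(tools::md5sum(f))
    ))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a structured fit report
#'
#' Writes the parameter estimates (`params.csv`), the implied genetic and
#' permanent covariance matrices (`U.csv`, `P.csv`), the heritability
#' trajectory (`heritability.csv`), fit statistics (`fit.json`) and a run
#' manifest into a directory.
#'
#' @param fit A `sad_fit`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @return Invisibly `out_dir`.
#' @export
write_fit_report <- function(fit, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(fit), file.path(out_dir, "params.csv"))
  write_matrix(fit$U, file.path(out_dir, "U.csv"))
  write_matrix(fit$P, file.path(out_dir, "P.csv"))
  readr::write_csv(heritability(fit), file.path(out_dir, "heritability.csv"))
  jsonlite::write_json(as.list(glance(fit)), file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(fit$convergence, file.path(out_dir, "convergence.csv"))
  write_manifest(out_dir, seed = seed,
                 extra = list(family = fit$family, logLik = fit$logLik,
                              AIC = fit$aic))
  invisible(out_dir)
}
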