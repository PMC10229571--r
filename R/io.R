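#' Write or read a survey as a directory of delimited files
#'
#' `write_survey()` writes the five survey tables as plain CSV
#' (`sites.csv`, `chamber_series.csv`, `water_samples.csv`,
#' `isotopes.csv`, `truth.csv`) plus the generator configuration as
#' `config.yaml`; `read_survey()` reads them back. Round-tripping a
#' survey through disk preserves all values to full printed precision
#' (15 significant digits).
#'
#' @param survey A `lake_survey` (see [generate_survey()]).
#' @param dir Directory to write into / read from (created if missing).
#' @return `write_survey()` returns `dir` invisibly; `read_survey()`
#'   returns a `lake_survey`.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "lake_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("sites", "chamber_series", "water_samples", "isotopes",
               "truth")) {
    df <- survey[[nm]]
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(survey$config))
    write_survey_config(survey$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  tabs <- lapply(c(sites = "sites", chamber_series = "chamber_series",
                   water_samples = "water_samples", isotopes = "isotopes",
                   truth = "truth"), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing survey table: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  })
  cfg_path <- file.path(dir, "config.yaml")
  tabs$config <- if (file.exists(cfg_path)) read_survey_config(cfg_path)
  structure(tabs, class = "lake_survey")
}
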