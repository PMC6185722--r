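# md5 checksums of the shipped fixture files, verified on load
FIXTURE_MD5 <- c(
  bgr_composition.csv     = "cb57ec58546c1106e25d55732bdcf477",
  bgr_properties.csv      = "250eda93f3ab19b61f29d047adc7cd35",
  bgr_turnover_fitted.csv = "734463f4714cfb341631e8069e25091e",
  published_screen_r2.csv = "4194ca0add11cb85e36a9be80446f888"
)

#' Load the bundled digestate reference tables
#'
#' The package ships the six-digestate reference panel as plain-text
#' fixtures: the substrate composition of each digestate (percent by
#' mass of maize silage, grass silage, rye silage, shredded grain, pig
#' slurry, cattle slurry, farmyard manure), the chemical properties (DM,
#' organic DM, pH, total C, NH4-N, organic N, total Kjeldahl N and the
#' C/N ratios, concentrations in percent of dry matter), the fitted
#' turnover parameters with their standard deviations and adaptation
#' RMSE, and the published screening R-squared column for comparison.
#' Files are checksum-verified on load.
#'
#' @param which One of `"composition"`, `"properties"`, `"parameters"`,
#'   `"published_r2"`, or `"all"` (default) for a named list.
#' @return A data.frame, or a named list of the four data.frames.
#' @examples
#' load_bgr_fixtures("properties")
#' @export
load_bgr_fixtures <- function(which = c("all", "composition", "properties",
                                        "parameters", "published_r2")) {
  which <- match.arg(which)
  files <- c(composition = "bgr_composition.csv",
             properties = "bgr_properties.csv",
             parameters = "bgr_turnover_fitted.csv",
             published_r2 = "published_screen_r2.csv")
  read_one <- function(f) {
    path <- system.file("extdata", f, package = "bgrsoc", mustWork = TRUE)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(FIXTURE_MD5[[f]])))
      stop(sprintf("corrupted install: checksum mismatch for %s", f),
           call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (which == "all") lapply(files, read_one) else read_one(files[[which]])
}
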