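FIELD_SOILS_MD5 <- "5d5e1c8a5abc00742d7e11d4107f44d3"

field_soils_path <- function() {
  system.file("extdata", "field_soils.csv", package = "cuaging",
              mustWork = TRUE)
}

#' The 20-soil European field-contamination dataset
#'
#' Twenty field soils contaminated with water-soluble Cu salts 8--78 years
#' before sampling, at sites in Denmark (Hygum), England (Woburn), the
#' Netherlands (Wageningen), Italy and Hungary. Columns: soil pH (0.01 M
#' CaCl2), annual-average site temperature (kelvin), contamination age
#' (years, converted to days at 365 d/y in column `time`), soil organic
#' carbon (% w/w), total Cu (mg/kg) and the measured labile fraction of
#' the Cu load (`e_add_obs`). This is the package's held-out validation
#' set: none of its rows enter parameter estimation.
#'
#' @param check If `TRUE` (default), verify the fixture file's md5 checksum
#'   and stop on mismatch.
#' @return Data frame with columns `sample_id`, `ph`, `corg`,
#'   `temperature`, `time` (days), `time_years`, `total_cu_mg_kg`,
#'   `e_add_obs`.
#' @examples
#' nrow(field_soils())  # 20
#' @export
field_soils <- function(check = TRUE) {
  path <- field_soils_path()
  if (check) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, FIELD_SOILS_MD5))
      stop("field_soils.csv checksum mismatch (expected ",
           FIELD_SOILS_MD5, ", got ", sum, "): fixture corrupted")
  }
  d <- read_observations(path)
  d[c("sample_id", "ph", "corg", "temperature", "time", "time_years",
      "total_cu_mg_kg", "e_add_obs")]
}

#' Validate the aging model against the field dataset
#'
#' Predicts the labile Cu fraction for the 20 field soils from soil pH,
#' organic carbon, site temperature and contamination age, and compares
#' with the measured isotope-dilution values: per-soil residuals, mean
#' absolute error and Pearson correlation.
#'
#' @param params An [aging_params()] object (default: the reference set).
#' @return List of class `field_validation`: `table` (per-soil measured,
#'   predicted, residual), `mae`, `pearson_r`, `n`.
#' @examples
#' v <- validate_field()
#' v$mae          # < 0.15
#' @export
validate_field <- function(params = aging_params()) {
  d <- field_soils()
  pred <- predict_e_add(d, params)
  tab <- data.frame(sample_id = d$sample_id,
                    e_add_obs = d$e_add_obs,
                    e_add_pred = pred$e_add_pred,
                    residual = d$e_add_obs - pred$e_add_pred,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 mae = mean(abs(tab$residual)),
                 pearson_r = cor(tab$e_add_obs, tab$e_add_pred),
                 n = nrow(tab)),
            class = "field_validation")
}

#' @export
print.field_validation <- function(x, ...) {
  cat("Field validation (20 long-term contaminated soils)\n")
  print(x$table, digits = 3, row.names = FALSE)
  cat(sprintf("  MAE = %.4f, Pearson r = %.3f, n = %d\n",
              x$mae, x$pearson_r, x$n))
  invisible(x)
}
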