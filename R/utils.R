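#' Thermal voltage RT/F
#'
#' Thermal voltage in millivolts at a given absolute temperature. Voltage
#' dependence of gating rates and Boltzmann curves is expressed per
#' \eqn{V_T = RT/F}; at room temperature (295.15 K) this is about 25.4 mV.
#'
#' @param temperature_K absolute temperature in Kelvin.
#' @return thermal voltage in mV.
#' @export
#' @examples
#' thermal_voltage()      # ~25.4 mV
#' thermal_voltage(310)   # body temperature
thermal_voltage <- function(temperature_K = 295.15) {
  stopifnot(is.finite(temperature_K), temperature_K > 0)
  1000 * 8.314462618 * temperature_K / 96485.33212
}

# Faraday constant in kcal/(mol*V), the unit system used for activation
# energies derived from (z, V1/2) pairs.
FARADAY_KCAL <- 23.06

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Atomic write: write to a temp file in the destination directory, then
# rename into place so readers never see a partial file.
#' @noRd
atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Write a data frame as tab-separated text
#'
#' Tab-separated with header, '.' decimal point, no quoting; written
#' atomically (temp file + rename).
#'
#' @param df data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  atomic_write(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Read tab-separated text written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Every stochastic operation in the package goes
# through this so identical seeds give identical output.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
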