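# Species call signatures: the harmonic-peak templates used for detection in
# spectral summaries.

#' Construct a call signature
#'
#' A call signature describes a species' call as a short list of harmonic
#' energy peaks -- (centre frequency, intensity offset in dB relative to the
#' loudest peak) -- plus the primary frequency band whose energy tracks
#' calling activity and the evening hours in which the species typically
#' calls.
#'
#' @param species Species identifier (string).
#' @param peaks Tibble or data frame with `freq_hz` and `rel_db` (<= 0; the
#'   loudest peak has offset 0). Peaks are stored sorted by frequency.
#' @param primary_band Numeric length-2: `[lo, hi)` in Hz, aligned to 100-Hz
#'   bins, within `[0, 11000)`.
#' @param typical_hours Integer hours (0--23) of typical calling.
#' @return A `wetscape_signature` list.
#' @export
call_signature <- function(species, peaks, primary_band, typical_hours) {
  peaks <- as_tibble(peaks)
  stopifnot(all(c("freq_hz", "rel_db") %in% names(peaks)))
  if (max(peaks$rel_db) != 0) {
    abort("call_signature(): loudest peak must have rel_db = 0")
  }
  if (any(peaks$rel_db > 0)) {
    abort("call_signature(): rel_db offsets must be <= 0")
  }
  stopifnot(length(primary_band) == 2, primary_band[1] < primary_band[2],
            primary_band[1] >= 0, primary_band[2] <= 11000,
            primary_band %% 100 == 0)
  stopifnot(all(typical_hours %in% 0:23))
  sig <- list(
    species = species,
    peaks = peaks %>% arrange(.data$freq_hz),
    primary_band = as.numeric(primary_band),
    typical_hours = sort(as.integer(typical_hours))
  )
  class(sig) <- "wetscape_signature"
  sig
}

#' @export
print.wetscape_signature <- function(x, ...) {
  cat(sprintf("<call signature: %s>\n", x$species))
  cat(sprintf("  peaks: %s\n", paste(
    sprintf("%d Hz (%+g dB)", x$peaks$freq_hz, x$peaks$rel_db),
    collapse = ", "
  )))
  cat(sprintf("  primary band: [%g, %g) Hz; hours: %s\n",
              x$primary_band[1], x$primary_band[2],
              paste(x$typical_hours, collapse = ",")))
  invisible(x)
}

#' Read and write call-signature files
#'
#' Signatures are stored as a YAML list: one entry per species with `peaks`
#' (list of `freq_hz`/`rel_db` pairs), `primary_band`, and `typical_hours`.
#'
#' @param signatures Named list of [call_signature()] objects.
#' @param path File path.
#' @return `write_signatures()` returns `path` invisibly;
#'   `read_signatures()` returns a named list of validated signatures.
#' @export
write_signatures <- function(signatures, path) {
  out <- lapply(signatures, function(s) {
    list(
      species = s$species,
      peaks = lapply(seq_len(nrow(s$peaks)), function(i) {
        list(freq_hz = s$peaks$freq_hz[i], rel_db = s$peaks$rel_db[i])
      }),
      primary_band = as.list(s$primary_band),
      typical_hours = as.list(s$typical_hours)
    )
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s) {
    call_signature(
      species = s$species,
      peaks = tibble(
        freq_hz = vapply(s$peaks, function(p) as.numeric(p$freq_hz),
                         numeric(1)),
        rel_db = vapply(s$peaks, function(p) as.numeric(p$rel_db),
                        numeric(1))
      ),
      primary_band = unlist(s$primary_band),
      typical_hours = unlist(s$typical_hours)
    )
  })
  setNames(out, vapply(out, function(s) s$species, character(1)))
}

#' Default signature set for north-central US wetland anurans
#'
#' Idealised harmonic-peak templates for the four early-season callers
#' monitored at the study wetlands: spring peeper (dominant harmonic near
#' 3 kHz), boreal chorus frog, gray treefrog complex, and wood frog. Peak
#' placements are spectrally disjoint so that template matching cannot
#' confuse the species.
#'
#' @return Named list of [call_signature()] objects.
#' @export
default_signatures <- function() {
  list(
    pseudacris_crucifer = call_signature(
      "pseudacris_crucifer",
      tibble(freq_hz = c(3000, 6000), rel_db = c(0, -18)),
      primary_band = c(2900, 3200),
      typical_hours = 19:23
    ),
    pseudacris_maculata = call_signature(
      "pseudacris_maculata",
      tibble(freq_hz = c(2500, 5000), rel_db = c(0, -15)),
      primary_band = c(2400, 2700),
      typical_hours = 18:23
    ),
    hyla_versicolor = call_signature(
      "hyla_versicolor",
      tibble(freq_hz = c(2200, 1100), rel_db = c(0, -12)),
      primary_band = c(2100, 2400),
      typical_hours = 20:23
    ),
    lithobates_sylvaticus = call_signature(
      "lithobates_sylvaticus",
      tibble(freq_hz = c(900, 1800), rel_db = c(0, -10)),
      primary_band = c(800, 1100),
      typical_hours = 15:22
    )
  )
}
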