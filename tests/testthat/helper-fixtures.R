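# Fixtures built in code: a small hand-laid valid label map, a minimal DICOM
# writer, and shared shorthand.

RC <- spinemark::REGION_CODES

# A 60x60 label map with a 2-disc spine stack that satisfies all six
# labeling requirements: Anterior | spine column | PosteriorA | PosteriorB.
toy_label_map <- function() {
  m <- matrix(RC[["Anterior"]], 60, 60)
  m[, 41:50] <- RC[["PosteriorA"]]
  m[, 51:60] <- RC[["PosteriorB"]]
  spine_cols <- 21:40
  m[51:58, spine_cols] <- RC[["Sacrum"]]
  m[46:50, spine_cols] <- RC[["IVD"]]
  m[36:45, spine_cols] <- RC[["Vertebrae"]]
  m[31:35, spine_cols] <- RC[["IVD"]]
  m[21:30, spine_cols] <- RC[["Vertebrae"]]
  spinemark::label_map(m, spinemark::image_meta(0.7292, 60))
}

# Minimal explicit-VR little-endian DICOM file written byte by byte.
write_test_dicom <- function(path, rows = 384L, cols = 384L,
                             spacing = c(0.7292, 0.7292),
                             pixel_values = NULL) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)

  short_el <- function(group, elem, vr, value_raw) {
    u16(group); u16(elem)
    writeChar(vr, con, eos = NULL)
    u16(length(value_raw))
    writeBin(value_raw, con)
  }
  ds <- function(x) {
    s <- paste(format(x, trim = TRUE), collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    charToRaw(s)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                             endian = "little")

  short_el(0x0002L, 0x0010L, "UI", {
    s <- charToRaw("1.2.840.10008.1.2.1")
    if (length(s) %% 2 == 1) s <- c(s, as.raw(0))  # UI pads with NUL
    s
  })
  short_el(0x0028L, 0x0010L, "US", us(rows))
  short_el(0x0028L, 0x0011L, "US", us(cols))
  short_el(0x0028L, 0x0030L, "DS", ds(spacing))
  short_el(0x0028L, 0x0100L, "US", us(16L))
  if (!is.null(pixel_values)) {
    u16(0x7fe0L); u16(0x0010L)
    writeChar("OW", con, eos = NULL)
    u16(0L)                                     # reserved
    u32(2L * length(pixel_values))
    writeBin(as.integer(pixel_values), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# A quiet phantom used by several suites: deterministic, no bumps.
quiet_phantom <- function(seed = 1L, n = 3L, grades = c(1L, 2L, 3L), ...) {
  spinemark::generate_phantom(spinemark::phantom_config(
    n_ivds = n, grades = grades, seed = seed, ...))
}
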