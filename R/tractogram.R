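# Tractogram container and TRK/TCK readers/writers.
#
# TRK (TrackVis): 1000-byte binary header, then per streamline an int32
# point count followed by float32 xyz triplets. Points on disk are in
# "voxmm" space with the origin at the corner of voxel (0,0,0): voxel
# center coordinates are voxmm / voxel_size - 0.5, and world coordinates
# follow from the header's vox_to_ras affine (header version 2).
#
# TCK (MRtrix): ASCII key/value header terminated by "END\n", then
# little-endian float32 xyz triplets in world (scanner) mm, streamlines
# separated by a NaN triplet and the stream terminated by an Inf triplet.

#' Construct a tractogram
#'
#' @param streamlines list of streamline matrices (n x 3, world mm, RAS).
#' @param affine 4x4 voxel-to-world affine of the reference image grid.
#' @param dim integer length-3 reference grid shape.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine = diag(4), dim = c(1L, 1L, 1L)) {
  check_affine(affine)
  streamlines <- lapply(streamlines, as_streamline)
  structure(list(streamlines = streamlines, affine = affine,
                 dim = as.integer(dim)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines, reference grid %s\n",
              length(x$streamlines), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

# drop streamlines with < 2 points or zero length; message the count
filter_degenerate <- function(streamlines) {
  ok <- vapply(streamlines, function(m) {
    is.matrix(m) && nrow(m) >= 2L && all(is.finite(m)) &&
      sum(abs(diff(m))) > 0
  }, logical(1))
  if (any(!ok))
    warning(sprintf("filtered %d degenerate streamline(s)", sum(!ok)),
            call. = FALSE)
  streamlines[ok]
}

read_fixed_string <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  raw <- raw[raw != as.raw(0)]
  rawToChar(raw)
}

#' Read a tractogram (TRK or TCK)
#'
#' Streamlines are returned in world mm, RAS. Degenerate streamlines
#' (fewer than 2 points, zero length) are filtered with a warning giving
#' the count.
#'
#' @param path path to a `.trk` or `.tck` file.
#' @return a `tractogram`.
#' @export
read_tractogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path),
         tck = read_tck(path),
         stop(sprintf("unsupported tractogram format '.%s' (need .trk or .tck)",
                      ext)))
}

#' Write a tractogram (TRK or TCK)
#'
#' @param tg a `tractogram` (streamlines in world mm RAS).
#' @param path destination `.trk` or `.tck` path.
#' @return the path, invisibly.
#' @export
write_tractogram <- function(tg, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(tg, path),
         tck = write_tck(tg, path),
         stop(sprintf("unsupported tractogram format '.%s' (need .trk or .tck)",
                      ext)))
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- read_fixed_string(con, 6L)
  if (!startsWith(id, "TRACK"))
    stop(sprintf("'%s' is not a TRK file (bad magic)", path))
  dims <- readBin(con, "integer", n = 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", n = 200))  # scalar names
  n_props <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", n = 200))  # property names
  vox2ras <- matrix(readBin(con, "numeric", n = 16, size = 4,
                            endian = "little"), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444))  # reserved
  invisible(read_fixed_string(con, 4L))    # voxel_order (affine is authoritative)
  invisible(readBin(con, "raw", n = 4))    # pad2
  invisible(readBin(con, "raw", n = 24))   # image_orientation_patient
  invisible(readBin(con, "raw", n = 2))    # pad1
  invisible(readBin(con, "raw", n = 6))    # invert/swap flags
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop(sprintf("'%s': unexpected TRK header size %d", path, hdr_size))
  if (all(vox2ras == 0))
    stop(sprintf("'%s': TRK header carries no vox_to_ras affine (version %d); space is unknown",
                 path, version))
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(np) == 0L) break
    pts <- matrix(readBin(con, "numeric", n = 3L * np + n_scalars * np,
                          size = 4, endian = "little"),
                  ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0)
      invisible(readBin(con, "numeric", n = n_props, size = 4,
                        endian = "little"))
    # voxmm (corner origin) -> voxel centers -> world
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    i <- i + 1L
    streamlines[[i]] <- voxel_to_world(vox, vox2ras)
  }
  streamlines <- filter_degenerate(streamlines[seq_len(i)])
  tractogram(streamlines, vox2ras, dims)
}

write_trk <- function(tg, path) {
  affine <- tg$affine
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(tg$dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")           # origin
  writeBin(0L, con, size = 2, endian = "little")                   # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")                   # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)                    # voxel_order
  writeBin(raw(4), con)                                            # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")           # orientation
  writeBin(raw(2), con)                                            # pad1
  writeBin(raw(6), con)                                            # invert flags
  writeBin(length(tg$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                   # version
  writeBin(1000L, con, size = 4, endian = "little")
  for (sl in tg$streamlines) {
    vox <- world_to_voxel(sl, affine)
    voxmm <- sweep(vox + 0.5, 2, voxel_size, "*")
    writeBin(nrow(sl), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tck <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header is ASCII up to the first "END\n"
  end_pat <- charToRaw("\nEND\n")
  hdr_end <- NA_integer_
  limit <- min(length(bytes), 65536L)
  for (i in seq_len(limit - length(end_pat) + 1L)) {
    if (all(bytes[i:(i + length(end_pat) - 1L)] == end_pat)) {
      hdr_end <- i + length(end_pat) - 1L
      break
    }
  }
  if (is.na(hdr_end)) stop(sprintf("'%s': no END marker in TCK header", path))
  lines <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\n", fixed = TRUE)[[1]]
  if (!identical(lines[1], "mrtrix tracks"))
    stop(sprintf("'%s' is not a TCK file (bad magic)", path))
  fields <- list()
  offset <- NA_integer_
  for (line in lines[-1]) {
    if (identical(line, "END")) break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    fields[[key]] <- val
    if (key == "file")
      offset <- as.integer(strsplit(val, "[[:space:]]+")[[1]][2])
  }
  dtype <- fields[["datatype"]]
  if (is.null(dtype) || !identical(dtype, "Float32LE"))
    stop(sprintf("'%s': unsupported TCK datatype '%s'", path,
                 if (is.null(dtype)) "<missing>" else dtype))
  if (is.na(offset)) stop(sprintf("'%s': TCK header lacks a file offset", path))
  raw_vals <- readBin(bytes[(offset + 1L):length(bytes)], "numeric",
                      n = (length(bytes) - offset) %/% 4L, size = 4,
                      endian = "little")
  m <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  for (r in seq_len(nrow(m))) {
    if (!all(is.finite(m[r, ]))) {
      if (r > start)
        streamlines[[length(streamlines) + 1L]] <- m[start:(r - 1L), ,
                                                     drop = FALSE]
      start <- r + 1L
      if (all(is.infinite(m[r, ]))) break
    }
  }
  streamlines <- filter_degenerate(streamlines)
  tractogram(streamlines)
}

write_tck <- function(tg, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(tg$streamlines)))
  # the 'file' line states its own byte offset; fix by two-pass sizing
  stub <- function(off) c(hdr, sprintf("file: . %d", off), "END")
  off <- 0L
  repeat {
    txt <- paste0(paste(stub(off), collapse = "\n"), "\n")
    if (nchar(txt, type = "bytes") == off) break
    off <- nchar(txt, type = "bytes")
  }
  writeChar(txt, con, eos = NULL)
  for (sl in tg$streamlines) {
    writeBin(as.numeric(t(sl)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}
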