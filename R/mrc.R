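# Minimal MRC2014 I/O (mode 2, 32-bit float, little-endian).
#
# The 1024-byte header is parsed/written field by field; only the fields
# the pipeline needs (grid size, mode, sampling, cell dimensions, axis
# order, density statistics) are interpreted. Cell dimensions are stored
# in Angstrom as usual, so voxel_size_nm = cella / (m* ) / 10.

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("corrupt MRC header: file too short")
  int_at <- function(i)
    readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer", size = 4L,
            endian = "little")
  flt_at <- function(i)
    readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "double", size = 4L,
            endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  nsymbt <- int_at(24)
  if (any(c(nx, ny, nz) < 1L) || any(c(nx, ny, nz) > 1e5))
    stop("corrupt MRC header: implausible grid size")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("unsupported MRC mode: ", mode)
  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))
  n <- as.numeric(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                             endian = "little")))
  if (length(vals) != n) stop("corrupt MRC file: truncated data block")
  vs <- rep(NA_real_, 3L)
  m3 <- c(mx, my, mz)
  ok <- m3 > 0L & is.finite(cella) & cella > 0
  vs[ok] <- cella[ok] / m3[ok] / 10  # Angstrom -> nm
  if (any(!ok)) vs <- NULL
  list(data = array(vals, c(nx, ny, nz)), voxel_size_nm = vs)
}

write_mrc <- function(arr, path, voxel_size_nm) {
  d <- dim(arr)
  voxel_size_nm <- rep_len(voxel_size_nm, 3L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                         # nx ny nz
  wi(2L)                        # mode 2: float32
  wi(c(0L, 0L, 0L))             # nxstart nystart nzstart
  wi(d)                         # mx my mz
  wf(d * voxel_size_nm * 10)    # cella (Angstrom)
  wf(c(90, 90, 90))             # cellb
  wi(c(1L, 2L, 3L))             # mapc mapr maps
  wf(c(min(arr), max(arr), mean(arr)))  # dmin dmax dmean
  wi(0L)                        # ispg
  wi(0L)                        # nsymbt
  writeBin(raw(100L), con)      # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(arr)))  # rms
  wi(0L)                        # nlabl
  writeBin(raw(800L), con)      # labels
  wf(as.vector(arr))
  invisible(path)
}
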