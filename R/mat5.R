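# Minimal reader/writer for MATLAB Level-5 MAT containers (the format used
# by -v6/-v7 saves; v7 wraps each variable in a zlib miCOMPRESSED element,
# which base memDecompress handles).  Only numeric (real) arrays are
# materialised; other classes are reported by name so callers can produce
# informative errors.  v7.3 files are HDF5 with a 512-byte user block and
# are handled separately (see read_mat73).

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_COMPRESSED <- 15L; MI_MATRIX <- 14L
MX_NUMERIC_CLASSES <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)

pad8 <- function(n) (8L - n %% 8L) %% 8L

read_mi_data <- function(con, type, nbytes, endian) {
  n <- switch(as.character(type),
    "1" = readBin(con, "integer", nbytes, size = 1L, signed = TRUE,
                  endian = endian),
    "2" = readBin(con, "integer", nbytes, size = 1L, signed = FALSE,
                  endian = endian),
    "3" = readBin(con, "integer", nbytes / 2L, size = 2L, signed = TRUE,
                  endian = endian),
    "4" = readBin(con, "integer", nbytes / 2L, size = 2L, signed = FALSE,
                  endian = endian),
    "5" = readBin(con, "integer", nbytes / 4L, size = 4L, endian = endian),
    "6" = readBin(con, "integer", nbytes / 4L, size = 4L, endian = endian),
    "7" = readBin(con, "double", nbytes / 4L, size = 4L, endian = endian),
    "9" = readBin(con, "double", nbytes / 8L, size = 8L, endian = endian),
    stop(sprintf("unsupported MAT data type %d", type)))
  as.numeric(n)
}

read_tag <- function(con, endian) {
  t <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(t) == 0L) return(NULL)
  if (bitwAnd(t, -65536L) != 0L) {          # small data element
    list(type = bitwAnd(t, 65535L), nbytes = bitwShiftR(t, 16L),
         small = TRUE)
  } else {
    nb <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    list(type = t, nbytes = nb, small = FALSE)
  }
}

# Read one sub/top-level element; returns list(name, value, class) where
# value is NULL for non-numeric classes.
read_element <- function(con, endian) {
  tag <- read_tag(con, endian)
  if (is.null(tag)) return(NULL)
  if (tag$type == MI_COMPRESSED) {
    raw <- readBin(con, "raw", tag$nbytes)
    inner <- rawConnection(memDecompress(raw, type = "gzip"))
    on.exit(close(inner))
    return(read_element(inner, endian))
  }
  if (tag$type != MI_MATRIX) {              # skip anything else
    readBin(con, "raw", tag$nbytes + if (tag$small) 0L else pad8(tag$nbytes))
    return(list(name = NA_character_, value = NULL, class = NA_integer_))
  }
  read_sub <- function() {
    st <- read_tag(con, endian)
    dat <- read_mi_data(con, st$type, st$nbytes, endian)
    if (!st$small) readBin(con, "raw", pad8(st$nbytes))
    list(type = st$type, data = dat)
  }
  flags <- read_sub()
  cls <- bitwAnd(as.integer(flags$data[1L]), 255L)
  complexf <- bitwAnd(as.integer(flags$data[1L]), 2048L) != 0L
  dims <- as.integer(read_sub()$data)
  nmtag <- read_tag(con, endian)
  nm <- rawToChar(readBin(con, "raw", nmtag$nbytes))
  if (!nmtag$small) readBin(con, "raw", pad8(nmtag$nbytes))
  if (!(cls %in% MX_NUMERIC_CLASSES))
    return(list(name = nm, value = NULL, class = cls))
  pr <- read_sub()
  if (complexf) read_sub()                  # imaginary part, discarded
  val <- array(pr$data, dim = dims)
  list(name = nm, value = val, class = cls)
}

#' Read a MAT (Level 5 / v7) container
#'
#' Reads every real numeric array variable from a MATLAB `-v6`/`-v7` MAT
#' file (zlib-compressed v7 elements are supported, both endiannesses).
#' Non-numeric variables are skipped but reported via the
#' `"skipped"` attribute.  For v7.3 (HDF5-based) files use [read_mat73()].
#'
#' @param path path to a `.mat` file.
#' @return Named list of numeric arrays in their on-disk (column-major,
#'   MATLAB) dimension order.
#' @seealso [write_mat()], [load_mat_movie()]
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  if (is_mat73(path))
    stop(sprintf("'%s' is a MAT v7.3 (HDF5) file; use read_mat73()", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 128L)
  if (length(hdr) < 128L) stop(sprintf("'%s' is not a MAT-file", path))
  marker <- rawToChar(hdr[127:128])
  endian <- switch(marker, IM = "little", MI = "big",
                   stop(sprintf("'%s' is not a Level-5 MAT-file", path)))
  out <- list(); skipped <- character()
  repeat {
    el <- tryCatch(read_element(con, endian), error = function(e) {
      stop(sprintf("I/O error reading '%s': %s", path, conditionMessage(e)))
    })
    if (is.null(el)) break
    if (is.null(el$value)) {
      if (!is.na(el$name)) skipped <- c(skipped, el$name)
    } else out[[el$name]] <- el$value
  }
  attr(out, "skipped") <- skipped
  out
}

is_mat73 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 128L)
  if (length(hdr) < 128L) return(FALSE)
  # v7.3 = HDF5 with 512-byte user block carrying the MAT text header
  ver <- readBin(hdr[125:126], "integer", 1L, size = 2L, signed = FALSE,
                 endian = if (rawToChar(hdr[127:128]) == "MI") "big"
                          else "little")
  isTRUE(ver == 512L)  # 0x0200
}

#' Read numeric arrays from a MAT v7.3 (HDF5) container
#'
#' v7.3 files are HDF5; no R HDF5 reader is assumed, so this routes through
#' the `h5py` library of the `python` interpreter on `PATH`.  Each root
#' numeric dataset is exported and re-read with MATLAB dimension order
#' restored.
#'
#' @param path path to a v7.3 `.mat` file.
#' @param python python executable to use.
#' @return Named list of numeric arrays (MATLAB dimension order).
#' @export
read_mat73 <- function(path, python = "python") {
  tmp <- tempfile("mat73_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- file.path(tmp, "dump.py")
  writeLines(c(
    "import sys, json, numpy as np, h5py",
    "path, out = sys.argv[1], sys.argv[2]",
    "meta = []",
    "with h5py.File(path, 'r') as f:",
    "    i = 0",
    "    for name, node in f.items():",
    "        if not isinstance(node, h5py.Dataset):",
    "            continue",
    "        arr = np.asarray(node)",
    "        if not np.issubdtype(arr.dtype, np.number):",
    "            continue",
    "        fn = out + '/' + str(i) + '.bin'",
    "        arr.astype('<f8').tofile(fn)",
    "        meta.append({'name': name, 'shape': list(arr.shape),",
    "                     'file': fn})",
    "        i += 1",
    "print(json.dumps(meta))"), script)
  res <- suppressWarnings(
    system2(python, c(script, shQuote(path), shQuote(tmp)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop(sprintf("h5py read of '%s' failed: %s", path,
                 paste(res, collapse = " ")))
  meta <- jsonlite_min_parse(res[length(res)])
  out <- list()
  for (m in meta) {
    dims <- rev(as.integer(unlist(m$shape)))   # HDF5 is row-major
    v <- readBin(m$file, "double", prod(dims), size = 8L,
                 endian = "little")
    out[[m$name]] <- array(v, dim = dims)
  }
  attr(out, "skipped") <- character()
  out
}

# tiny JSON parser shim: prefer jsonlite when present (Suggests), else a
# minimal parser sufficient for the dump metadata emitted above
jsonlite_min_parse <- function(txt) {
  if (requireNamespace("jsonlite", quietly = TRUE))
    return(jsonlite::fromJSON(txt, simplifyVector = FALSE))
  stop("reading v7.3 metadata requires the jsonlite package")
}

write_mi_tagged <- function(con, type, raw_writer, nbytes, endian) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = endian)
  raw_writer()
  np <- pad8(nbytes)
  if (np > 0L) writeBin(raw(np), con)
}

#' Write numeric arrays to a MAT (Level 5) container
#'
#' Writes each element of `vars` as a double-precision real array readable
#' by MATLAB (`-v6`/`-v7`) and by [read_mat()].  With `compress = TRUE`
#' each variable is wrapped in a zlib `miCOMPRESSED` element (the v7
#' convention).
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output path.
#' @param compress compress each variable with zlib.
#' @export
write_mat <- function(vars, path, compress = FALSE) {
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    stop("all variables must be named")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by omapr %s",
                  as.character(packageVersion("omapr")))
  hdr <- charToRaw(formatC(desc, width = -116))
  hdr <- c(hdr[seq_len(min(116L, length(hdr)))],
           raw(116L - min(116L, length(hdr))))
  hdr[hdr == as.raw(0L)] <- charToRaw(" ")
  writeBin(hdr, con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100, little-endian
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) stop(sprintf("variable '%s' is not numeric", nm))
    dims <- dim(v)
    if (is.null(dims)) dims <- length(v)
    if (length(dims) == 1L) dims <- c(dims, 1L)
    body <- matrix_element_raw(as.numeric(v), as.integer(dims), nm)
    if (compress) {
      z <- memCompress(body, type = "gzip")
      writeBin(as.integer(c(MI_COMPRESSED, length(z))), con, size = 4L,
               endian = "little")
      writeBin(z, con)
      np <- pad8(length(z))
      if (np > 0L) writeBin(raw(np), con)
    } else {
      writeBin(body, con)
    }
  }
  invisible(path)
}

# serialise one miMATRIX element (tag included) to raw, little-endian
matrix_element_raw <- function(v, dims, name) {
  rcon <- rawConnection(raw(0L), "wb")
  on.exit(close(rcon))
  wtag <- function(type, nbytes)
    writeBin(as.integer(c(type, nbytes)), rcon, size = 4L,
             endian = "little")
  wpad <- function(n) if (pad8(n) > 0L) writeBin(raw(pad8(n)), rcon)
  # array flags: class double (6), no flags
  wtag(MI_UINT32, 8L); writeBin(c(6L, 0L), rcon, size = 4L,
                                endian = "little")
  nd <- length(dims) * 4L
  wtag(MI_INT32, nd); writeBin(dims, rcon, size = 4L, endian = "little")
  wpad(nd)
  nmraw <- charToRaw(name)
  wtag(MI_INT8, length(nmraw)); writeBin(nmraw, rcon); wpad(length(nmraw))
  wtag(MI_DOUBLE, 8L * length(v))
  writeBin(v, rcon, size = 8L, endian = "little")
  body <- rawConnectionValue(rcon)
  c(writeBin(as.integer(c(MI_MATRIX, length(body))), raw(), size = 4L,
             endian = "little"), body)
}
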