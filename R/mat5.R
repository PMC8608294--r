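# Minimal MAT-v5 container reader: dense numeric (and logical) 2-D arrays
# only, uncompressed or zlib-compressed elements. Enough to load deposited
# association datasets; cells, structs, sparse and complex arrays are
# skipped with a warning.

.MI_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
               `7` = 4L, `9` = 8L)

.readMiData <- function(raw, type, nbytes, endian) {
  n <- nbytes %/% .MI_SIZES[[as.character(type)]]
  out <- switch(as.character(type),
    `1` = readBin(raw, "integer", n, size = 1, signed = TRUE,
                  endian = endian),
    `2` = readBin(raw, "integer", n, size = 1, signed = FALSE,
                  endian = endian),
    `3` = readBin(raw, "integer", n, size = 2, signed = TRUE,
                  endian = endian),
    `4` = readBin(raw, "integer", n, size = 2, signed = FALSE,
                  endian = endian),
    `5` = readBin(raw, "integer", n, size = 4, endian = endian),
    `6` = {
      v <- readBin(raw, "integer", n, size = 4, endian = endian)
      v <- as.double(v); v[v < 0] <- v[v < 0] + 2^32; v
    },
    `7` = readBin(raw, "double", n, size = 4, endian = endian),
    `9` = readBin(raw, "double", n, size = 8, endian = endian),
    stop(sprintf("unsupported MAT data type %d", type)))
  as.double(out)
}

# returns list(type, data (raw), next offset); handles small-element format
# (miCOMPRESSED elements are not padded to the 8-byte boundary)
.readElement <- function(raw, pos, endian) {
  tag <- readBin(raw[pos + 0:3], "integer", 1, size = 4, endian = endian)
  small <- bitwAnd(tag, -65536L)  # upper 16 bits nonzero => small element
  if (small != 0L) {
    type <- bitwAnd(tag, 65535L)
    nbytes <- bitwShiftR(bitwAnd(tag, -65536L), 16)
    data <- raw[pos + 4:(3 + nbytes)]
    if (nbytes == 0) data <- raw(0)
    list(type = type, nbytes = nbytes, data = data, nxt = pos + 8L)
  } else {
    type <- tag
    nbytes <- readBin(raw[pos + 4:7], "integer", 1, size = 4,
                      endian = endian)
    data <- if (nbytes > 0) raw[pos + 8:(7 + nbytes)] else raw(0)
    pad <- if (type == 15L) 0L else (8L - nbytes %% 8L) %% 8L
    list(type = type, nbytes = nbytes, data = data,
         nxt = pos + 8L + nbytes + pad)
  }
}

.parseMatrixElement <- function(raw, endian) {
  pos <- 1L
  flagsEl <- .readElement(raw, pos, endian); pos <- flagsEl$nxt
  flags <- readBin(flagsEl$data[1:4], "integer", 1, size = 4,
                   endian = endian)
  cls <- bitwAnd(flags, 255L)
  if (bitwAnd(flags, 2048L) != 0L) return(NULL)  # complex: skip
  dimsEl <- .readElement(raw, pos, endian); pos <- dimsEl$nxt
  dims <- readBin(dimsEl$data, "integer", dimsEl$nbytes %/% 4L, size = 4,
                  endian = endian)
  nameEl <- .readElement(raw, pos, endian); pos <- nameEl$nxt
  name <- rawToChar(nameEl$data[nameEl$data != as.raw(0)])
  if (!(cls %in% 6:13) || length(dims) != 2) return(list(name = name))
  dataEl <- .readElement(raw, pos, endian)
  vals <- .readMiData(dataEl$data, dataEl$type, dataEl$nbytes, endian)
  if (length(vals) != prod(dims)) return(list(name = name))
  list(name = name, value = matrix(vals, dims[1], dims[2]))
}

#' Read numeric arrays from a MAT-v5 container
#'
#' Parses the dense numeric 2-D arrays of a Level-5 MAT file into a named
#' list of R matrices (column-major, as stored). Compressed elements are
#' inflated with \code{memDecompress}; unsupported array classes are
#' skipped with a warning.
#'
#' @param path path to the \code{.mat} file.
#' @return Named list of numeric matrices.
#' @export
readMat5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) stop("not a MAT-v5 file: truncated header")
  magic <- rawToChar(raw[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop("not a MAT-v5 file: bad endian indicator")
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- .readElement(raw, pos, endian)
    pos <- el$nxt
    if (el$type == 15L) {  # miCOMPRESSED: zlib stream wrapping one element
      inner <- tryCatch(memDecompress(el$data, type = "gzip"),
                        error = function(e) NULL)
      if (is.null(inner)) {
        warning("could not inflate a compressed MAT element; skipped")
        next
      }
      iel <- .readElement(inner, 1L, endian)
      if (iel$type != 14L) next
      parsed <- .parseMatrixElement(iel$data, endian)
    } else if (el$type == 14L) {
      parsed <- .parseMatrixElement(el$data, endian)
    } else next
    if (is.null(parsed)) next
    if (is.null(parsed$value)) {
      warning(sprintf("MAT variable '%s' has an unsupported class; skipped",
                      parsed$name))
      next
    }
    nm <- if (nzchar(parsed$name)) parsed$name else
      sprintf("var%d", length(out) + 1L)
    out[[nm]] <- parsed$value
  }
  out
}

#' Load a deposited association dataset from a MAT-v5 container
#'
#' Maps the container's arrays onto an \linkS4class{AssociationMatrix} plus
#' optional precomputed lncRNA/disease similarity matrices. Variable
#' discovery is heuristic by shape (the association candidate is the first
#' non-square 0/1 array, or the only array) with explicit overrides, since
#' deposited files do not document their variable names.
#'
#' @param path path to the \code{.mat} file.
#' @param ldVar,llVar,ddVar optional variable names overriding the shape
#'   heuristic for the association matrix and the precomputed lncRNA /
#'   disease similarity matrices.
#' @return A list with elements \code{assoc}
#'   (\linkS4class{AssociationMatrix}), \code{ll} and \code{dd} (numeric
#'   similarity matrices or \code{NULL}).
#' @export
loadMatDataset <- function(path, ldVar = NULL, llVar = NULL, ddVar = NULL) {
  vars <- readMat5(path)
  if (!length(vars)) stop("no 2-D numeric array found in MAT container")
  pick <- function(nm) {
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(vars))
      stop(sprintf("variable '%s' not found in MAT container", nm))
    vars[[nm]]
  }
  ld <- pick(ldVar)
  if (is.null(ld)) {
    nonsq <- vars[vapply(vars, function(m) nrow(m) != ncol(m), TRUE)]
    ld <- if (length(nonsq)) nonsq[[1]]
          else if (length(vars) == 1) vars[[1]]
          else stop("ambiguous MAT container: specify ldVar")
  }
  bad <- setdiff(unique(as.vector(ld)), c(0, 1))
  if (length(bad))
    stop(sprintf("association candidate is not binary; offending values: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  nl <- nrow(ld); nd <- ncol(ld)
  assoc <- AssociationMatrix(ld, lncrnaIds = sprintf("l%03d", seq_len(nl)),
                             diseaseIds = sprintf("d%03d", seq_len(nd)))
  sq <- function(side, override) {
    if (!is.null(override)) return(pick(override))
    hit <- vars[vapply(vars, function(m)
      nrow(m) == side && ncol(m) == side, TRUE)]
    if (length(hit)) hit[[1]] else NULL
  }
  list(assoc = assoc, ll = sq(nl, llVar), dd = sq(nd, ddVar))
}
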