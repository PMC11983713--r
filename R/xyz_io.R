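#' Read an XYZ or extended-XYZ file
#'
#' Plain XYZ (count, comment, `elem x y z` lines) and the de-facto extended
#' dialect where the comment line carries `Lattice="ax ay az bx by bz cx cy
#' cz"` and a `Properties=...` column declaration.  A per-atom column named
#' `charge` is returned alongside the configuration; only orthorhombic
#' lattices are accepted.  Multi-frame files are read with [read_xyz_frames()].
#'
#' @param path file path.
#' @return a [configuration()]; per-atom charges, when present, in attribute
#'   `"charges"`.
#' @export
read_xyz <- function(path) {
  frames <- read_xyz_frames(path, max_frames = 1L)
  frames[[1]]
}

#' @rdname read_xyz
#' @param max_frames maximum number of frames to read (default all).
#' @return for `read_xyz_frames`, a list of configurations.
#' @export
read_xyz_frames <- function(path, max_frames = Inf) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && length(frames) < max_frames) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("XYZ parse error at line ", i, ": expected atom count")
    n <- as.integer(lines[i])
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    if (i + 1L + n > length(lines))
      stop("XYZ parse error: truncated frame starting at line ", i)
    at <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(at), "\\s+")
    ncol_at <- unique(lengths(toks))
    if (length(ncol_at) != 1 || ncol_at[1] < 4)
      stop("XYZ parse error: malformed atom line near line ", i + 2L)
    species <- vapply(toks, `[[`, "", 1L)
    num <- matrix(suppressWarnings(as.numeric(unlist(lapply(toks, `[`,
                                                            -1L)))),
                  nrow = n, byrow = TRUE)
    if (anyNA(num))
      stop("XYZ parse error: non-numeric field near line ", i + 2L)
    cell <- NULL
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 1) {
      v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                               "\\s+")[[1]])
      if (length(v) != 9) stop("bad Lattice entry in XYZ comment line")
      L <- matrix(v, 3, 3, byrow = TRUE)
      if (max(abs(L - diag(diag(L)))) > 1e-10)
        stop("only orthorhombic lattices are supported")
      cell <- diag(L)
    }
    charges <- NULL
    # column layout from Properties=...; default species + pos (+ charge)
    prop <- regmatches(comment, regexpr("Properties=\\S+", comment))
    qcol <- NULL
    if (length(prop) == 1) {
      fields <- strsplit(sub("Properties=", "", prop), ":")[[1]]
      # triplets name:type:count
      names_ <- fields[seq(1, length(fields), by = 3)]
      counts <- as.integer(fields[seq(3, length(fields), by = 3)])
      colpos <- cumsum(c(0, counts[-length(counts)]))
      if ("charge" %in% names_) {
        # numeric columns exclude the species column
        k <- which(names_ == "charge")
        qcol <- colpos[k] - counts[which(names_ == "species")][1] + 1L
      }
    } else if (ncol(num) >= 4) {
      qcol <- 4L
    }
    if (!is.null(qcol) && qcol <= ncol(num)) charges <- num[, qcol]
    cfg <- configuration(species, num[, 1:3, drop = FALSE], cell = cell)
    if (!is.null(charges)) attr(cfg, "charges") <- charges
    frames[[length(frames) + 1L]] <- cfg
    i <- i + 2L + n
  }
  frames
}

#' Write a configuration (or frames) as extended XYZ
#'
#' The lattice is emitted as nine floats in the comment line and columns are
#' declared through a `Properties` string; a per-atom `charge` column is
#' written when charges are given.  Numbers use 12 significant digits so a
#' write/read round trip is an identity at printed precision.
#'
#' @param config a configuration or list of configurations.
#' @param path output path.
#' @param charges optional per-atom charge vector (or list, one per frame).
#' @param append append to an existing file.
#' @export
write_xyz <- function(config, path, charges = NULL, append = FALSE) {
  frames <- if (inherits(config, "aq_config")) list(config) else config
  if (!is.null(charges) && !is.list(charges)) charges <- list(charges)
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    cfg <- frames[[f]]
    q <- if (!is.null(charges)) charges[[f]] else attr(cfg, "charges")
    n <- nrow(cfg$positions)
    props <- if (is.null(q)) "Properties=species:S:1:pos:R:3"
             else "Properties=species:S:1:pos:R:3:charge:R:1"
    comment <- props
    if (!is.null(cfg$cell)) {
      l <- cfg$cell
      comment <- sprintf(
        'Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" %s', l[1], l[2], l[3], props)
    }
    writeLines(c(sprintf("%d", n), comment), con)
    for (i in seq_len(n)) {
      line <- sprintf("%s %.12g %.12g %.12g", cfg$species[i],
                      cfg$positions[i, 1], cfg$positions[i, 2],
                      cfg$positions[i, 3])
      if (!is.null(q)) line <- sprintf("%s %.12g", line, q[i])
      writeLines(line, con)
    }
  }
  invisible(path)
}
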