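# Readers and writers for the community-standard interchange formats:
# TPS landmark files, long-format landmark CSV, FASTA barcodes.

#' Read landmark configurations from a TPS file
#'
#' Parses the classic TPS dialect: \code{LM=k} opens a record of k coordinate
#' lines; \code{ID=}, \code{SCALE=} and \code{IMAGE=} keys are honoured
#' (\code{SCALE} multiplies coordinates, converting digitizer units to mm);
#' unknown keys are skipped with a warning.  Population labels come from a
#' sidecar table when given, otherwise from the id prefix before the first
#' \code{"_"}.
#'
#' @param path path to a TPS file.
#' @param populations optional named character vector or two-column
#'   data.frame (\code{id}, \code{population}) mapping specimen ids to
#'   population labels; authoritative when present.
#' @return A [WingDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=p1_a",
#'              "LM=3", "0 0", "2 0", "0 2", "ID=p2_b"), tf)
#' readTPS(tf)
#' @export
readTPS <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  recs <- list()
  i <- 1L
  recno <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("expected 'LM=' at line ", i, " of ", path)
    recno <- recno + 1L
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L)
      stop("record ", recno, ": malformed LM count")
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (r in seq_len(k)) {
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", lines[i]))
        stop("record ", recno, ": expected ", k,
             " coordinate lines but found ", r - 1L)
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[,[:space:]]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("record ", recno, ": malformed coordinate line '", lines[i], "'")
      coords[r, ] <- xy
      i <- i + 1L
    }
    id <- NULL; scale <- 1
    while (i <= length(lines) && grepl("^[A-Za-z]+\\s*=", lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      else if (key == "SCALE") scale <- as.numeric(val)
      else if (key != "IMAGE")
        warning("record ", recno, ": ignoring unknown TPS key '", key, "'")
      i <- i + 1L
    }
    if (is.null(id)) id <- sprintf("specimen_%03d", recno)
    recs[[recno]] <- list(id = id, coords = coords * scale)
  }
  if (!length(recs)) stop("no records in ", path)
  ks <- vapply(recs, function(r) nrow(r$coords), 0L)
  if (length(unique(ks)) != 1L)
    stop("landmark count differs across records: ",
         paste(unique(ks), collapse = ", "))
  ids <- vapply(recs, `[[`, "", "id")
  pop <- resolvePopulations(ids, populations)
  WingDataset(lapply(recs, `[[`, "coords"),
              data.frame(id = ids, population = pop))
}

resolvePopulations <- function(ids, populations) {
  if (is.null(populations))
    return(sub("_.*$", "", ids))
  if (is.data.frame(populations))
    populations <- setNames(as.character(populations$population),
                            populations$id)
  miss <- setdiff(ids, names(populations))
  if (length(miss))
    stop("no population label for specimen(s): ", paste(miss, collapse = ", "))
  unname(populations[ids])
}

#' Write a WingDataset as a TPS file
#'
#' @param x a [WingDataset-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTPS <- function(x, path) {
  stopifnot(is(x, "WingDataset"))
  k <- landmarkCount(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nSpecimens(x))) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(apply(x@coords[, , i], 1, function(p)
      paste(sprintf("%.17g", p), collapse = " ")), con)
    writeLines(sprintf("ID=%s", x@specimens$id[i]), con)
  }
  invisible(path)
}

#' Read/write landmark configurations in long-format CSV
#'
#' The layout is one landmark per row with columns \code{specimen},
#' \code{population}, \code{landmark} (1-based index), \code{x}, \code{y}
#' (mm).  \code{writeLandmarkCSV} emits full-precision decimal text so a
#' write/read round trip reproduces coordinates exactly.
#'
#' @param path CSV path.
#' @param schema named character vector remapping the expected column names,
#'   e.g. \code{c(specimen = "wing_id")}.
#' @return \code{readLandmarkCSV}: a [WingDataset-class].
#' @export
readLandmarkCSV <- function(path, schema = NULL) {
  cols <- c(specimen = "specimen", population = "population",
            landmark = "landmark", x = "x", y = "y")
  if (!is.null(schema)) cols[names(schema)] <- schema
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  d <- d[, cols]
  names(d) <- names(cols)
  if (anyDuplicated(d[, c("specimen", "landmark")]))
    stop("duplicated (specimen, landmark index) pair(s) in ", path)
  ids <- unique(d$specimen)
  k <- max(d$landmark)
  confs <- vector("list", length(ids))
  pops <- character(length(ids))
  for (i in seq_along(ids)) {
    di <- d[d$specimen == ids[i], ]
    if (!setequal(di$landmark, seq_len(k)))
      stop("specimen ", ids[i], ": missing landmark index(es) ",
           paste(setdiff(seq_len(k), di$landmark), collapse = ", "))
    di <- di[order(di$landmark), ]
    confs[[i]] <- cbind(di$x, di$y)
    pops[i] <- di$population[1]
  }
  WingDataset(confs, data.frame(id = ids, population = pops))
}

#' @rdname readLandmarkCSV
#' @param x a [WingDataset-class] to write.
#' @export
writeLandmarkCSV <- function(x, path) {
  stopifnot(is(x, "WingDataset"))
  k <- landmarkCount(x)
  n <- nSpecimens(x)
  d <- data.frame(
    specimen = rep(x@specimens$id, each = k),
    population = rep(x@specimens$population, each = k),
    landmark = rep(seq_len(k), n),
    x = sprintf("%.17g", as.vector(apply(x@coords, 3, function(m) m[, 1]))),
    y = sprintf("%.17g", as.vector(apply(x@coords, 3, function(m) m[, 2]))))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read population-labelled barcode sequences from FASTA
#'
#' Population labels are parsed from a header token: headers of the form
#' \code{id<token>population} yield the label after the first occurrence of
#' \code{token} (default \code{"|"}).  When the token is absent the label
#' falls back to \code{fallback}.
#'
#' @param path FASTA file.
#' @param token separator between specimen id and population in the header.
#' @param fallback label used when no token is present.
#' @return A [BarcodeSet-class]; sequences keep their read order.
#' @export
readBarcodeFasta <- function(path, token = "|", fallback = "unknown") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path)
  hdr <- names(seqs)
  parts <- strsplit(hdr, token, fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  pop <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else fallback, "")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  names(seqs) <- ids
  BarcodeSet(seqs, pop)
}

#' Write a BarcodeSet as FASTA with population-tagged headers
#'
#' @param x a [BarcodeSet-class].
#' @param path output path.
#' @param token separator placed between id and population in headers.
#' @return \code{path}, invisibly.
#' @export
writeBarcodeFasta <- function(x, path, token = "|") {
  stopifnot(is(x, "BarcodeSet"))
  out <- x@sequences
  names(out) <- paste0(names(x@sequences), token, x@population)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Check and mark alignment status of a BarcodeSet
#'
#' @param x a [BarcodeSet-class].
#' @return TRUE when all sequences have equal length (an alignment), else
#'   FALSE.
#' @export
isAligned <- function(x) {
  stopifnot(is(x, "BarcodeSet"))
  length(unique(Biostrings::width(x@sequences))) == 1L
}
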