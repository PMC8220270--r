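#' @include AllGenerics.R
NULL

#' Construct a LimbMeasurements table
#'
#' @param lengths numeric matrix of bone lengths, specimens in rows and
#'   elements in columns (mm; `NA` for missing cells). Column names must
#'   match `elements`.
#' @param specimen_id,species character vectors, one entry per row of
#'   `lengths`; specimen ids must be unique.
#' @param life_stage `"embryo"`, `"hatchling"` or `"adult"`, recycled if
#'   scalar.
#' @param size_proxy positive numeric body-size proxy per specimen (spine
#'   length in mm for embryos/hatchlings, pelvic-girdle centroid size for
#'   adults).
#' @param stage optional numeric staging-table stage (embryos: 11-19).
#' @param elements ordered element names; defaults to the columns of
#'   `lengths`.
#' @param log_scale whether values are already natural-log transformed.
#' @param missing_cap maximum tolerated missing fraction (default 10%).
#' @return a [LimbMeasurements] object.
#' @export
#' @examples
#' m <- matrix(rexp(12) + 1, 2, 6,
#'             dimnames = list(NULL, limbElements("forelimb")))
#' lm6 <- LimbMeasurements(m, specimen_id = c("a", "b"),
#'                         species = c("sp1", "sp1"),
#'                         life_stage = "embryo", size_proxy = c(10, 12))
#' missingFraction(lm6)
LimbMeasurements <- function(lengths, specimen_id, species,
                             life_stage, size_proxy, stage = NULL,
                             elements = colnames(lengths),
                             log_scale = FALSE, missing_cap = 0.10) {
  lengths <- as.matrix(lengths)
  if (is.null(elements))
    stop("element names are required (column names of 'lengths')")
  if (!identical(colnames(lengths), as.character(elements)))
    lengths <- lengths[, elements, drop = FALSE]
  n <- nrow(lengths)
  life_stage <- rep_len(as.character(life_stage), n)
  cd <- S4Vectors::DataFrame(
    specimen_id = as.character(specimen_id),
    species = as.character(species),
    life_stage = life_stage,
    size_proxy = as.numeric(size_proxy))
  if (!is.null(stage)) cd$stage <- as.numeric(rep_len(stage, n))
  mf <- mean(is.na(lengths))
  if (mf > missing_cap)
    stop(sprintf("missing fraction %.1f%% exceeds the cap of %.1f%%",
                 100 * mf, 100 * missing_cap))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lengths = t(lengths)),
    colData = cd)
  colnames(se) <- cd$specimen_id
  S4Vectors::metadata(se)$log_scale <- isTRUE(log_scale)
  new("LimbMeasurements", se)
}

#' @rdname LimbMeasurements-class
#' @return `measurementMatrix`: specimens-by-elements numeric matrix.
#' @export
setMethod("measurementMatrix", "LimbMeasurements", function(x)
  t(SummarizedExperiment::assay(x, "lengths")))

#' @rdname LimbMeasurements-class
#' @export
setMethod("speciesOf", "LimbMeasurements", function(x)
  SummarizedExperiment::colData(x)$species)

#' @rdname LimbMeasurements-class
#' @export
setMethod("lifeStage", "LimbMeasurements", function(x)
  SummarizedExperiment::colData(x)$life_stage)

#' @rdname LimbMeasurements-class
#' @export
setMethod("sizeProxy", "LimbMeasurements", function(x)
  SummarizedExperiment::colData(x)$size_proxy)

#' @rdname LimbMeasurements-class
#' @export
setMethod("isLogScale", "LimbMeasurements", function(x)
  isTRUE(S4Vectors::metadata(x)$log_scale))

#' @rdname LimbMeasurements-class
#' @return `missingFraction`: fraction of element cells that are `NA`.
#' @export
setMethod("missingFraction", "LimbMeasurements", function(x)
  mean(is.na(SummarizedExperiment::assay(x, "lengths"))))

setMethod("show", "LimbMeasurements", function(object) {
  cat(sprintf(
    "LimbMeasurements: %d specimens x %d elements (%s scale)\n",
    ncol(object), nrow(object),
    if (isLogScale(object)) "log" else "linear"))
  sp <- speciesOf(object)
  cat(sprintf("  species: %d | stages: %s | missing: %.2f%%\n",
              length(unique(sp)),
              paste(unique(lifeStage(object)), collapse = "/"),
              100 * missingFraction(object)))
  cat("  elements:", paste(rownames(object), collapse = ", "), "\n")
})

#' Read a measurement table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing
#' `specimen_id`, `species`, `life_stage`, `size_proxy`, optionally `stage`,
#' and one column per element. Missing cells are empty strings or `NA`.
#' Lengths are on the linear scale (mm).
#'
#' @param path CSV file path.
#' @param elements ordered element names expected in the file, e.g.
#'   [limbElements()]. Extra columns are ignored.
#' @param missing_cap maximum tolerated missing fraction.
#' @return a [LimbMeasurements] object.
#' @export
readMeasurements <- function(path, elements = limbElements("forelimb"),
                             missing_cap = 0.10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  need <- c("specimen_id", "species", "life_stage", "size_proxy",
            as.character(elements))
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("schema error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  M <- as.matrix(df[, as.character(elements), drop = FALSE])
  storage.mode(M) <- "double"
  bad <- which(!is.na(M) & M <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("validation error: non-positive length in row(s) ",
         paste(unique(bad[, 1L]), collapse = ", "))
  LimbMeasurements(M, specimen_id = df$specimen_id, species = df$species,
                   life_stage = df$life_stage, size_proxy = df$size_proxy,
                   stage = if ("stage" %in% colnames(df)) df$stage,
                   elements = as.character(elements),
                   missing_cap = missing_cap)
}

#' Write a measurement table to CSV
#'
#' Inverse of [readMeasurements()]; a complete linear-scale table
#' round-trips bit-identically through write and read.
#' @param x a [LimbMeasurements] object.
#' @param path output CSV path.
#' @export
writeMeasurements <- function(x, path) {
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(specimen_id = cd$specimen_id, species = cd$species,
                   life_stage = cd$life_stage, size_proxy = cd$size_proxy,
                   stringsAsFactors = FALSE)
  if ("stage" %in% colnames(cd)) df$stage <- cd$stage
  df <- cbind(df, as.data.frame(measurementMatrix(x)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @rdname logTransform
#' @export
setMethod("logTransform", "LimbMeasurements", function(x) {
  if (isLogScale(x))
    stop("table is already on the log scale; refusing to transform twice")
  A <- SummarizedExperiment::assay(x, "lengths")
  if (any(!is.na(A) & A <= 0))
    stop("non-positive lengths cannot be log-transformed")
  SummarizedExperiment::assay(x, "lengths") <- log(A)
  SummarizedExperiment::colData(x)$size_proxy <-
    log(SummarizedExperiment::colData(x)$size_proxy)
  S4Vectors::metadata(x)$log_scale <- TRUE
  validObject(x)
  x
})

#' @rdname speciesMeans
#' @export
setMethod("speciesMeans", "LimbMeasurements", function(x) {
  M <- measurementMatrix(x)
  if (anyNA(M)) stop("species means require a complete table; impute first")
  sp <- speciesOf(x)
  f <- factor(sp, levels = unique(sp))
  Mm <- apply(M, 2L, function(col) tapply(col, f, mean))
  if (is.null(dim(Mm))) Mm <- matrix(Mm, nrow = 1L,
                                     dimnames = list(levels(f), colnames(M)))
  szm <- as.numeric(tapply(sizeProxy(x), f, mean))
  st <- tapply(lifeStage(x), f, function(s)
    if (length(unique(s)) == 1L) s[[1L]] else s[[1L]])
  LimbMeasurements(Mm, specimen_id = levels(f), species = levels(f),
                   life_stage = as.character(st), size_proxy = szm,
                   elements = colnames(M),
                   log_scale = isLogScale(x))
})

#' Read a species-to-group map
#'
#' Two-column CSV (`species`, `group`) assigning each species to a major
#' biogeographic group: `Ant` (Antillean), `MLpri` (Primary Mainland),
#' `MLsec` (Secondary Mainland) or `other`. Species mapped to `other` are
#' treated as excluded from group-level analyses.
#' @param path CSV file path.
#' @return named character vector, species to group.
#' @export
readGroupMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("species", "group") %in% colnames(df)))
    stop("schema error: group map needs columns 'species' and 'group'")
  bad <- setdiff(unique(df$group), .GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$group, df$species)
}

#' Check that every species in a table is mapped or explicitly excluded
#' @param x a [LimbMeasurements] object.
#' @param groups named character vector from [readGroupMap()].
#' @param excluded species deliberately left out.
#' @return invisibly, the species-to-group assignments for `x`.
#' @export
checkGroupCoverage <- function(x, groups, excluded = character()) {
  sp <- unique(speciesOf(x))
  unmapped <- setdiff(sp, c(names(groups), excluded))
  if (length(unmapped))
    stop("species neither mapped to a group nor excluded: ",
         paste(unmapped, collapse = ", "))
  invisible(groups[intersect(sp, names(groups))])
}
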