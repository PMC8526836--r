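# Plain-text interchange: square matrices (connectomes, FC) as TSV with a
# header row of region labels; FIC solutions and fit results as JSON.

#' Write / read a labelled square matrix as TSV
#'
#' @param x a \code{connectome}, \code{fc_matrix}, or square matrix.
#' @param path output file.
#' @export
write_matrix_tsv <- function(x, path) {
  M <- if (inherits(x, "connectome")) x$C
       else if (inherits(x, "fc_matrix")) x$R else x
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (is.null(colnames(M))) colnames(M) <- sprintf("R%02d", seq_len(ncol(M)))
  utils::write.table(M, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param as return type: plain \code{"matrix"}, \code{"connectome"} or
#'   \code{"fc_matrix"}.
#' @export
read_matrix_tsv <- function(path, as = c("matrix", "connectome", "fc_matrix")) {
  as <- match.arg(as)
  M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(M) <- colnames(M)
  switch(as,
         matrix = M,
         connectome = structure(list(labels = colnames(M), C = M),
                                class = "connectome"),
         fc_matrix = structure(list(R = M, labels = colnames(M)),
                               class = "fc_matrix"))
}

#' Serialize a FIC solution to JSON
#'
#' @param fic a \code{fic_solution}.
#' @param path output file.
#' @param labels optional region labels.
#' @export
write_fic_json <- function(fic, path, labels = NULL) {
  jsonlite::write_json(
    list(labels = labels %||% sprintf("R%02d", seq_along(fic$J)),
         J = fic$J, achieved_rates = fic$achieved_rates,
         converged = fic$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write gene lists as one-id-per-line text
#'
#' @param genes character vector of gene ids.
#' @param path output file.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) readLines(path)

#' Write / read voxel timeseries as 4-D NIfTI
#'
#' Places the voxel timeseries back on their regular 3-D grid (x, y, z,
#' time). Physical voxel size is carried in the header in millimetres.
#' Grid cells not covered by the dataset are zero-filled.
#'
#' @param ds a \code{voxel_dataset} (fields \code{data}, \code{coords}).
#' @param path output file (.nii or .nii.gz).
#' @export
write_voxels_nifti <- function(ds, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  co <- as.matrix(ds$coords)
  sp <- apply(co, 2, function(x) {
    d <- diff(sort(unique(x)))
    if (length(d)) min(d) else 1
  })
  idx <- round(sweep(co, 2, sp, "/")) + 1L
  dims <- apply(idx, 2, max)
  arr <- array(0, c(dims, ncol(ds$data)))
  for (v in seq_len(nrow(co)))
    arr[idx[v, 1], idx[v, 2], idx[v, 3], ] <- ds$data[v, ]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp / 1000, ds$tr_s %||% 1)  # um -> mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxels_nifti
#' @param tr_s repetition time override; taken from the header when NULL.
#' @export
read_voxels_nifti <- function(path, tr_s = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI input")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4)
  pd <- RNifti::pixdim(img)
  grid <- as.matrix(expand.grid(x = seq_len(dim(arr)[1]),
                                y = seq_len(dim(arr)[2]),
                                z = seq_len(dim(arr)[3])))
  coords <- sweep(grid - 1L, 2, pd[1:3] * 1000, "*")  # mm -> um
  data <- matrix(aperm(arr, c(4, 1, 2, 3)), nrow = dim(arr)[4])
  structure(list(data = t(data), coords = coords,
                 mask = rep(TRUE, nrow(coords)),
                 tr_s = if (is.null(tr_s)) pd[4] else tr_s),
            class = "voxel_dataset")
}
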