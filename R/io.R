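# File-format adapters: NIfTI-1 volumes (via RNifti), RDM / similarity
# matrices as headered CSV, triplet and rating tables as TSV.

#' Read a 3-D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3-D array with the NIfTI attributes preserved.
#' @export
read_volume <- function(path) {
  vol <- RNifti::readNifti(path)
  if (length(dim(vol)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(vol)), "-D: ", path)
  vol
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (length(dim(vol)) != 3L) stop("expected a 3-D volume")
  RNifti::writeNifti(RNifti::asNifti(vol + 0), path)
  invisible(path)
}

#' Read an RDM from headered CSV
#'
#' The file must be square with matching row/column labels; symmetry is
#' enforced by averaging the two halves (beyond `1e-8` asymmetry is an
#' error) and the diagonal is forced to zero with a warning when nonzero.
#'
#' @param path CSV path.
#' @return A labelled RDM matrix.
#' @export
read_rdm_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop("RDM file is not square: ", path)
  if (anyDuplicated(rownames(M))) stop("duplicate RDM labels: ", path)
  if (max(abs(M - t(M))) > 1e-8)
    stop("RDM asymmetric beyond tolerance: ", path)
  M <- (M + t(M)) / 2
  if (max(abs(diag(M))) > 1e-8)
    warning("nonzero RDM diagonal forced to 0: ", path)
  diag(M) <- 0
  M
}

#' Write an RDM (or any labelled square matrix) as headered CSV
#'
#' @param R Matrix with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rdm_csv <- function(R, path) {
  utils::write.csv(as.data.frame(R), path, row.names = TRUE)
  invisible(path)
}

#' Write / read triplet response tables as TSV
#'
#' Columns `item_a`, `item_b`, `item_c`, `odd`.
#'
#' @param triplets Data frame of triplet responses.
#' @param path TSV path.
#' @return `write_triplets_tsv` the path invisibly; `read_triplets_tsv` the
#'   data frame.
#' @export
write_triplets_tsv <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_triplets_tsv
#' @export
read_triplets_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("item_a", "item_b", "item_c", "odd")
  if (!all(need %in% names(df)))
    stop("triplet table must have columns ", paste(need, collapse = ", "))
  df
}
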