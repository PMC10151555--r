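# Virtual screening: score a compound library with a QSAR model, rank,
# threshold into hits, and annotate the applicability domain.

#' Screen a compound library with a QSAR model
#'
#' Computes the model's descriptors for every library entry, predicts pIC50,
#' ranks entries by predicted activity (descending, ties broken by id) and
#' flags hits at `threshold_pic50` (default 8, i.e. predicted IC50 <= 10 nM).
#' Entries whose structure or descriptors cannot be computed are counted and
#' reported, never silently dropped.
#'
#' @param library a path to an SDF/SMILES file, a list of [molecule()]
#'   objects, or a descriptor data.frame whose row names are library ids.
#' @param model a `"qsar_mlr"`; defaults to the published arginase-I
#'   equation.
#' @param threshold_pic50 hit threshold on predicted pIC50.
#' @param params [surface_params()] for descriptor computation.
#' @return object of class `"hit_table"`: `entries` (data.frame id,
#'   predicted_pic50, is_hit, rank, descriptor columns), `counts`
#'   (screened / scored / failed / hits), `threshold_pic50`, `failures`.
#' @export
screen_library <- function(library, model = published_arginase_model(),
                           threshold_pic50 = 8.0,
                           params = surface_params()) {
  failures <- character()
  if (is.character(library) && length(library) == 1L) {
    library <- read_structures(library)
  }
  if (is.data.frame(library) || is.matrix(library)) {
    X <- as.data.frame(library)
    n_in <- nrow(X)
  } else {
    if (inherits(library, "molecule")) library <- list(library)
    if (!length(library)) stop("empty screening library")
    n_in <- length(library)
    X <- suppressWarnings(compute_descriptors(library, pool = "model6",
                                              params = params))
    failures <- attr(X, "failed")
  }
  if (!nrow(X)) stop("no library entry could be scored")
  pred <- predict(model, X)
  ids <- rownames(X)
  ord <- order(-pred, ids)
  entries <- data.frame(id = ids[ord], predicted_pic50 = pred[ord],
                        X[ord, , drop = FALSE],
                        row.names = NULL, check.names = FALSE)
  entries$is_hit <- entries$predicted_pic50 >= threshold_pic50
  entries$rank <- seq_len(nrow(entries))
  structure(list(
    entries = entries,
    threshold_pic50 = threshold_pic50,
    counts = c(screened = n_in, scored = nrow(entries),
               failed = length(failures), hits = sum(entries$is_hit)),
    failures = failures,
    model = model),
    class = "hit_table")
}

#' @export
print.hit_table <- function(x, n = 10, ...) {
  cat(sprintf("Virtual screen: %d screened, %d scored, %d failed, %d hits (pIC50 >= %.2f)\n",
              x$counts["screened"], x$counts["scored"], x$counts["failed"],
              x$counts["hits"], x$threshold_pic50))
  cols <- intersect(c("rank", "id", "predicted_pic50", "leverage", "in_domain"),
                    names(x$entries))
  print(utils::head(x$entries[, cols], n))
  invisible(x)
}

#' Annotate screening hits with applicability-domain information
#'
#' Adds leverage and in-domain flags to every entry of a hit table, using
#' the training descriptor block of a fitted model: h = x (X'X)^-1 x',
#' h* = 3 (p + 1) / n_train, in-domain iff h <= h*.
#'
#' @param hits a `"hit_table"` from [screen_library()].
#' @param train_model a fitted [qsar_mlr()] providing the training block
#'   (X of the training compounds).
#' @return the hit table with `leverage` and `in_domain` columns and an
#'   `h_star` element.
#' @export
annotate_ad <- function(hits, train_model) {
  stopifnot(inherits(hits, "hit_table"))
  lev <- leverage_analysis(train_model,
                           hits$entries[, train_model$descriptor_names,
                                        drop = FALSE])
  hits$entries$leverage <- lev$h
  hits$entries$in_domain <- lev$in_domain
  hits$h_star <- lev$h_star
  hits
}
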