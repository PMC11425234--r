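# Signature curation: the Boruta-confirmed features are filtered to genes
# positively associated with disease progression (deg_call "up") that carry a
# mouse ortholog, then ordered by descending per-NAS-unit effect. The result
# is the unified human-mouse severity signature used for ssGSEA staging.

#' Curate the unified severity signature
#'
#' Retains genes that are Boruta-confirmed AND called `up` in the severity
#' DE table AND present in the ortholog map; orders them by descending
#' `beta_nas`. Each member records its mouse ortholog (fan-outs resolved to
#' the `one_to_one` partner, else the lexicographically smallest mouse gene)
#' and the four provenance flags.
#'
#' @param boruta `boruta_result` from [boruta_select()].
#' @param de `DETable` with `deg_call` filled by [call_severity_degs()].
#' @param orth Ortholog map data frame.
#' @return A `gene_signature` data frame: `gene`, `mouse_gene`, `direction`
#'   (always `"up"`), `beta_nas`, and logical flags `deg`,
#'   `boruta_confirmed`, `positive_assoc`, `has_ortholog`. Empty (with a
#'   warning) when no gene survives.
#' @export
curate_signature <- function(boruta, de, orth) {
  confirmed <- boruta$feature[boruta$status == "confirmed"]
  de_idx <- match(confirmed, de$gene_id)
  if (anyNA(de_idx))
    stop("Boruta features missing from the DE table: ",
         paste(utils::head(confirmed[is.na(de_idx)], 3L), collapse = ", "))
  keep <- de$deg_call[de_idx] == "up" & confirmed %in% orth$human_gene
  genes <- confirmed[keep]
  sig <- data.frame(gene = genes,
                    mouse_gene = vapply(genes, resolve_ortholog, character(1L),
                                        orth = orth, quiet = TRUE),
                    direction = rep("up", length(genes)),
                    beta_nas = de$beta_nas[match(genes, de$gene_id)],
                    deg = rep(TRUE, length(genes)),
                    boruta_confirmed = rep(TRUE, length(genes)),
                    positive_assoc = rep(TRUE, length(genes)),
                    has_ortholog = rep(TRUE, length(genes)),
                    stringsAsFactors = FALSE)
  sig <- sig[order(-sig$beta_nas, sig$gene), , drop = FALSE]
  rownames(sig) <- NULL
  if (nrow(sig) == 0L)
    warning("signature curation retained no genes")
  class(sig) <- c("gene_signature", "data.frame")
  sig
}

# Mouse partner for one human gene: prefer the one_to_one pair, otherwise the
# lexicographically smallest mouse partner.
resolve_ortholog <- function(gene, orth, quiet = FALSE) {
  rows <- orth[orth$human_gene == gene, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_character_)
  if (nrow(rows) == 1L) return(rows$mouse_gene)
  oto <- rows$mouse_gene[rows$one_to_one]
  if (length(oto) >= 1L) return(sort(oto)[1L])
  pick <- sort(rows$mouse_gene)[1L]
  if (!quiet)
    warning("gene '", gene, "' has ", nrow(rows),
            " mouse partners, none one-to-one; using '", pick, "'")
  pick
}

#' Translate a signature across species
#'
#' Maps the signature membership into the target species' gene namespace,
#' preserving order. Fan-out orthologs resolve to the `one_to_one` partner
#' when available, otherwise to the lexicographically smallest target gene
#' (with a warning).
#'
#' @param sig `gene_signature` from [curate_signature()] (or a character
#'   vector of human genes).
#' @param orth Ortholog map data frame.
#' @param to Target species: `"mouse"` or `"human"`.
#' @return Character vector of target-species gene identifiers, in signature
#'   order.
#' @export
translate_signature <- function(sig, orth, to = c("mouse", "human")) {
  to <- match.arg(to)
  genes <- if (inherits(sig, "gene_signature")) sig$gene else as.character(sig)
  if (to == "human") return(genes)
  out <- vapply(genes, resolve_ortholog, character(1L), orth = orth)
  if (anyNA(out))
    stop("no mouse ortholog for: ",
         paste(genes[is.na(out)], collapse = ", "))
  unname(out)
}
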