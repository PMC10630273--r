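# Lytic-role classification: product-keyword rules, domain evidence, and
# per-protein domain architectures.

ENDOLYSIN_KEYWORDS <- c("n-acetylmuramoyl-l-alanine amidase", "endolysin",
                        "phage lysin", "lysin")
HOLIN_KEYWORD <- "holin"

LYTIC_ROLES <- c("endolysin", "holin", "holin_like", "other_lytic", "unknown")

#' Classify a product string into a lytic role
#'
#' Case-insensitive substring matching on the annotation keywords used to
#' locate lysis genes in GenBank records: "N-acetylmuramoyl-L-alanine
#' amidase", "endolysin", "phage lysin" and "lysin" assign `endolysin`;
#' "holin" assigns `holin`; anything else (including the empty string) is
#' `unknown`. Endolysin keywords are checked first, so "endolysin" and
#' "phage lysin" are never mistaken for holins, and "lysin" subsumes
#' "endolysin" harmlessly.
#'
#' @param product free-text product annotation (may be empty).
#' @return one of `"endolysin"`, `"holin"`, `"unknown"`.
#' @export
classify_by_keyword <- function(product) {
  p <- tolower(product)
  if (any(vapply(ENDOLYSIN_KEYWORDS, grepl, logical(1), x = p, fixed = TRUE)))
    return("endolysin")
  if (grepl(HOLIN_KEYWORD, p, fixed = TRUE)) return("holin")
  "unknown"
}

# merge overlapping hits of the same canonical name to their envelope;
# different names are kept even when overlapping (repeat domains survive)
merge_domain_hits <- function(dom) {
  if (!nrow(dom)) return(dom)
  dom <- dom[order(dom$start_aa, dom$end_aa), , drop = FALSE]
  out <- dom[0, , drop = FALSE]
  for (i in seq_len(nrow(dom))) {
    j <- which(out$canonical_name == dom$canonical_name[i] &
                 out$end_aa >= dom$start_aa[i])
    if (length(j)) {
      j <- j[length(j)]
      out$end_aa[j] <- max(out$end_aa[j], dom$end_aa[i])
    } else out <- rbind(out, dom[i, , drop = FALSE])
  }
  out <- out[order(out$start_aa, out$end_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a protein with a lytic role and domain architecture
#'
#' Combines the product-keyword rule with signature-domain evidence. Role
#' precedence (highest first): a holin-family domain, an XhlA domain
#' (holin-like), a catalytic domain (endolysin), a CWB-only architecture
#' (other lytic), the keyword role, unknown. Domain evidence therefore
#' outranks the keyword on conflict — this encodes the practice of
#' confirming keyword hits with a domain scan, and rescues lysis genes
#' annotated as "hypothetical protein" or "tail fiber protein".
#' Overlapping hits of the same canonical name are merged to their
#' envelope interval; repeat domains of different positions survive.
#'
#' @param feature a [cds_feature()].
#' @param hits data.frame of domain hits for this protein (may be empty);
#'   rows with `protein_id` different from the feature's are rejected.
#' @param vocab vocabulary data.frame.
#' @return an object of class `protein_architecture`: list with
#'   `protein_id`, `role`, `domains` (data.frame `canonical_name`,
#'   `category`, `start_aa`, `end_aa`, N-to-C ordered) and `evidence`
#'   (`"keyword"`, `"domain"` or `"both"`).
#' @export
annotate_protein <- function(feature, hits = NULL, vocab = default_vocabulary()) {
  empty_dom <- data.frame(canonical_name = character(0), category = character(0),
                          start_aa = integer(0), end_aa = integer(0),
                          stringsAsFactors = FALSE)
  dom <- empty_dom
  if (!is.null(hits) && nrow(hits)) {
    if (!all(hits$protein_id == feature$protein_id))
      stopf("hits for foreign protein id passed to annotate_protein(%s)",
            feature$protein_id)
    tlen <- nchar(feature$translation)
    if (tlen > 0 && any(hits$end_aa > tlen))
      stopf("protein %s: domain hit end %d exceeds translation length %d",
            feature$protein_id, max(hits$end_aa), tlen)
    for (i in seq_len(nrow(hits))) {
      m <- map_signature(hits$signature_accession[i], vocab)
      if (is.null(m)) next
      dom <- rbind(dom, data.frame(canonical_name = m$canonical_name,
                                   category = m$category,
                                   start_aa = hits$start_aa[i],
                                   end_aa = hits$end_aa[i],
                                   stringsAsFactors = FALSE))
    }
    dom <- merge_domain_hits(dom)
  }
  kw_role <- classify_by_keyword(feature$product)
  cats <- dom$category
  dom_role <- if ("holin" %in% cats) "holin" else
    if ("holin_like" %in% cats) "holin_like" else
      if ("catalytic" %in% cats) "endolysin" else
        if (nrow(dom) && all(cats == "cwb")) "other_lytic" else NA_character_
  if (!is.na(dom_role)) {
    role <- dom_role
    evidence <- if (kw_role == role) "both" else "domain"
  } else if (kw_role != "unknown") {
    role <- kw_role
    evidence <- "keyword"
  } else if (nrow(dom)) {
    role <- "other_lytic"   # e.g. accessory domains added via vocabulary
    evidence <- "domain"
  } else {
    role <- "unknown"
    evidence <- "keyword"
  }
  structure(list(protein_id = feature$protein_id, role = role,
                 domains = dom, evidence = evidence),
            class = "protein_architecture")
}

#' Annotate every CDS of a genome
#'
#' @param genome a [genome_record()].
#' @param hits data.frame of domain hits (any proteins; filtered by
#'   protein id per CDS).
#' @param vocab vocabulary data.frame.
#' @return list of `protein_architecture`, one per CDS, in genomic order.
#' @export
annotate_genome <- function(genome, hits = NULL, vocab = default_vocabulary()) {
  lapply(genome$cds, function(f) {
    h <- if (is.null(hits)) NULL else
      hits[hits$protein_id == f$protein_id, , drop = FALSE]
    annotate_protein(f, h, vocab)
  })
}

#' @export
print.protein_architecture <- function(x, ...) {
  archi <- if (nrow(x$domains))
    paste(x$domains$canonical_name, collapse = " -> ") else "(no domains)"
  cat(sprintf("<protein_architecture> %s: %s [%s; evidence=%s]\n",
              x$protein_id, x$role, archi, x$evidence))
  invisible(x)
}
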