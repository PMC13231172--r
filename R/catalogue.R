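# The labeled contact catalogue (a-z): 10 stacks + 16 H-bond contacts
# spanning the A site, the CAR site and the A/CAR interface.

#' Define a single labeled contact
#'
#' A contact is a `stack` (ring-COG distance between the two partner
#' residues) or an `hbond` (family of donor-hydrogen-acceptor candidates
#' between them, enumerated from the edge catalogue at evaluation time unless
#' `candidates` is given explicitly).
#'
#' @param label contact label (single letter in the default catalogue).
#' @param kind `"stack"` or `"hbond"`.
#' @param a,b partner residues, each `list(chain =, resno =)`.
#' @param site one of `"A_site"`, `"CAR_site"`, `"interface"`.
#' @param group for `hbond` contacts, the mRNA nucleotide this contact is
#'   grouped under for site-level H-bond strength (e.g. `"M4"`); `NA` for
#'   stacks.
#' @param reconstructed logical; `FALSE` where the letter assignment is fixed
#'   by the published catalogue, `TRUE` where it is a documented
#'   reconstruction.
#' @param candidates optional explicit list of [hbondSpec()] candidates.
#' @return a contact definition (named list).
#' @seealso [defaultCatalogue()]
#' @export
contactDef <- function(label, kind = c("stack", "hbond"), a, b,
                       site = c("A_site", "CAR_site", "interface"),
                       group = NA_character_, reconstructed = TRUE,
                       candidates = NULL) {
  kind <- match.arg(kind)
  site <- match.arg(site)
  stopifnot(is.list(a), is.list(b),
            all(c("chain", "resno") %in% names(a)),
            all(c("chain", "resno") %in% names(b)))
  if (kind == "stack" && !is.null(candidates))
    stop("stack contacts take ring systems from the ring catalogue, ",
         "not hbond candidates")
  list(label = as.character(label), kind = kind,
       partners = list(a = a, b = b), site = site, group = group,
       reconstructed = isTRUE(reconstructed), candidates = candidates)
}

#' Build a contact catalogue from definitions
#' @param contacts list of [contactDef()] definitions.
#' @return a [ContactCatalogue-class].
#' @export
contactCatalogue <- function(contacts)
  new("ContactCatalogue", contacts = contacts)

#' @rdname contactLabels
#' @export
setMethod("contactLabels", "ContactCatalogue", function(x)
  vapply(x@contacts, function(ct) ct$label, ""))

#' @describeIn ContactCatalogue-class number of contacts.
#' @param x a `ContactCatalogue`.
#' @export
setMethod("length", "ContactCatalogue", function(x) length(x@contacts))

#' @describeIn ContactCatalogue-class extract one contact by index or label.
#' @param i index or label.
#' @param j,... unused.
#' @export
setMethod("[[", "ContactCatalogue", function(x, i, j, ...) {
  if (is.character(i)) i <- match(i, contactLabels(x))
  x@contacts[[i]]
})

setMethod("show", "ContactCatalogue", function(object) {
  tab <- catalogueTable(object)
  cat("ContactCatalogue with", length(object), "contacts (",
      sum(tab$kind == "stack"), "stacks,",
      sum(tab$kind == "hbond"), "H-bond families )\n")
  print(tab, row.names = FALSE)
})

#' Tabular view of a contact catalogue
#' @param catalogue a [ContactCatalogue-class].
#' @return data.frame with one row per contact.
#' @export
catalogueTable <- function(catalogue) {
  do.call(rbind, lapply(catalogue@contacts, function(ct) data.frame(
    label = ct$label, kind = ct$kind,
    a = paste0(ct$partners$a$chain, ":", ct$partners$a$resno),
    b = paste0(ct$partners$b$chain, ":", ct$partners$b$resno),
    site = ct$site, group = ct$group, reconstructed = ct$reconstructed,
    stringsAsFactors = FALSE)))
}

# residue layout of the decoding-center neighborhood used by the default
# catalogue and the synthetic generator:
#   chain T: tRNA anticodon 34 (always G), 35, 36
#   chain M: mRNA 1..3 = A-site codon N1..N3, 4..6 = +1 codon N1..N3
#   chain C: 18S/16S rRNA CAR residues 1054 (C) and 1196 (A)
#   chain P: Rps3 protein, residue 146 (ARG)
.res <- function(chain, resno) list(chain = chain, resno = resno)

#' The default 26-contact catalogue (a-z)
#'
#' Ten stack pairs spanning the anticodon (36:35, 35:34), the anticodon:CAR
#' tether (34:C1054), CAR internal stacks (C:A pi-pi, A:R pi-cation), the
#' A-site codon (N1:N2, N2:N3), the inter-codon bridge (N3:+1N1) and the +1
#' codon (+1N1:+1N2, +1N2:+1N3); plus sixteen H-bond contacts pairing each
#' mRNA nucleotide with its nearest residues on the complementary surface
#' (anticodon residues for the A site; tRNA-34/C1054/A1196/R146 for the CAR
#' side, with `s`, `t`, `u` the +1N1 contacts to 34, C-of-CAR and A-of-CAR).
#' Letter assignments that are not fixed by the published labeling carry
#' `reconstructed = TRUE` and can be overridden via [contactCatalogue()].
#'
#' @return a [ContactCatalogue-class] of length 26 (10 stacks, 16 H-bonds).
#' @examples
#' cat26 <- defaultCatalogue()
#' length(cat26)
#' catalogueTable(cat26)
#' @export
defaultCatalogue <- function() {
  T34 <- .res("T", 34); T35 <- .res("T", 35); T36 <- .res("T", 36)
  M <- lapply(1:6, function(i) .res("M", i))
  CC <- .res("C", 1054); CA <- .res("C", 1196); CR <- .res("P", 146)
  st <- function(label, a, b, site, rec = FALSE)
    contactDef(label, "stack", a, b, site, reconstructed = rec)
  hb <- function(label, a, b, site, group, rec = TRUE)
    contactDef(label, "hbond", a, b, site, group = group, reconstructed = rec)
  contactCatalogue(list(
    # the ten stack gaps, anticodon/CAR column then mRNA column
    st("a", T36, T35, "A_site"),
    st("b", T35, T34, "A_site"),
    st("c", T34, CC, "interface"),
    st("d", CC, CA, "CAR_site"),
    st("e", CA, CR, "CAR_site"),
    st("f", M[[1]], M[[2]], "A_site"),
    st("g", M[[2]], M[[3]], "A_site"),
    st("h", M[[3]], M[[4]], "interface"),
    st("i", M[[4]], M[[5]], "CAR_site"),
    st("j", M[[5]], M[[6]], "CAR_site"),
    # A-site H-bonds: codon nucleotides vs nearest anticodon residues
    hb("k", M[[1]], T36, "A_site", "M1"),
    hb("l", M[[1]], T35, "A_site", "M1"),
    hb("m", M[[1]], T34, "A_site", "M1"),
    hb("n", M[[2]], T36, "A_site", "M2"),
    hb("o", M[[2]], T35, "A_site", "M2"),
    hb("p", M[[2]], T34, "A_site", "M2"),
    hb("q", M[[3]], T35, "A_site", "M3"),
    hb("r", M[[3]], T34, "A_site", "M3"),
    # CAR-side H-bonds: +1 codon nucleotides vs 34/C/A/R surface
    hb("s", M[[4]], T34, "interface", "M4", rec = FALSE),
    hb("t", M[[4]], CC, "CAR_site", "M4", rec = FALSE),
    hb("u", M[[4]], CA, "CAR_site", "M4", rec = FALSE),
    hb("v", M[[5]], CC, "CAR_site", "M5"),
    hb("w", M[[5]], CA, "CAR_site", "M5"),
    hb("x", M[[5]], CR, "CAR_site", "M5"),
    hb("y", M[[6]], CA, "CAR_site", "M6"),
    hb("z", M[[6]], CR, "CAR_site", "M6")
  ))
}

#' Read/write a contact catalogue as JSON
#'
#' The external, editable representation of a catalogue: one object per
#' contact with label, kind, partner residue references, site tag, group and
#' the reconstructed flag.
#'
#' @param catalogue a [ContactCatalogue-class].
#' @param path JSON file path.
#' @return `readCatalogueJSON()` returns a [ContactCatalogue-class];
#'   `writeCatalogueJSON()` returns `path` invisibly.
#' @export
writeCatalogueJSON <- function(catalogue, path) {
  jsonlite::write_json(
    lapply(catalogue@contacts, function(ct)
      ct[c("label", "kind", "partners", "site", "group", "reconstructed")]),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeCatalogueJSON
#' @export
readCatalogueJSON <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  contactCatalogue(lapply(raw, function(ct)
    contactDef(ct$label, ct$kind,
               a = ct$partners$a, b = ct$partners$b, site = ct$site,
               group = if (is.null(ct$group)) NA_character_ else ct$group,
               reconstructed = isTRUE(ct$reconstructed))))
}
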