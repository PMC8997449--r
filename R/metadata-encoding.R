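## One-hot encoding of patient metadata: sex (2), anatomic site (8) and
## 5-year age group (18) concatenate into a fixed 28-dimensional binary
## feature vector. Category order follows the printed coding tables and is
## frozen in the codebook; a missing field encodes as an all-zero block.

#' The canonical metadata codebook
#'
#' Ordered category lists for the three clinical fields and their
#' cardinalities (2 + 8 + 18 = 28). The ordering is fixed: sex is
#' (female, male) — so female encodes (1,0) and male (0,1) — sites are
#' alphabetical, ages run 0, 5, ..., 85.
#'
#' @return object of class `metadata_codebook` with elements `sex`,
#'   `anatom_site`, `age` and `dims`.
#' @export
metadata_codebook <- function() {
  structure(list(
    sex = c("female", "male"),
    anatom_site = c("anterior torso", "head/neck", "lateral torso",
                    "lower extremity", "oral/genital", "palms/soles",
                    "posterior torso", "upper extremity"),
    age = seq(0L, 85L, by = 5L),
    dims = c(sex = 2L, anatom_site = 8L, age = 18L)),
    class = "metadata_codebook")
}

one_hot <- function(value, categories, field) {
  v <- numeric(length(categories))
  if (length(value) == 0 || is.na(value)) return(v)  # missing -> zero block
  pos <- match(value, categories)
  if (is.na(pos))
    stop(sprintf("unknown %s category: %s", field, value), call. = FALSE)
  v[pos] <- 1
  v
}

#' Encode a single metadata field
#'
#' `NA` encodes as an all-zero block; an unrecognised category is an error
#' (ages are not rounded to the 5-year grid — off-grid values are rejected).
#'
#' @param value `"male"`/`"female"`, one of the eight anatomic sites, or an
#'   age in `{0, 5, ..., 85}`; `NA` for missing.
#' @param codebook a [metadata_codebook()].
#' @return binary vector of length 2, 8 or 18 with at most one 1.
#' @export
#' @examples
#' encode_sex("male")           # 0 1
#' encode_site("anterior torso")
#' encode_age(85)
encode_sex <- function(value, codebook = metadata_codebook()) {
  one_hot(value, codebook$sex, "sex")
}

#' @rdname encode_sex
#' @export
encode_site <- function(value, codebook = metadata_codebook()) {
  one_hot(value, codebook$anatom_site, "anatomic site")
}

#' @rdname encode_sex
#' @export
encode_age <- function(value, codebook = metadata_codebook()) {
  if (!is.na(value) && !(value %in% codebook$age))
    stop(sprintf("age %s is not on the 5-year grid 0, 5, ..., 85", value),
         call. = FALSE)
  one_hot(value, codebook$age, "age")
}

#' Encode a metadata record as the 28-dimensional feature vector
#'
#' Concatenates the three one-hot blocks in the layout
#' `[sex (2) | site (8) | age (18)]`. Encoding is a pure function of the
#' codebook, and [decode_vector()] inverts it exactly for non-missing
#' records.
#'
#' @param record list or one-row data.frame with fields `sex`,
#'   `anatom_site`, `age` (each possibly `NA`).
#' @param codebook a [metadata_codebook()].
#' @return numeric binary vector of length 28.
#' @export
#' @examples
#' v <- encode_record(list(sex = "male", anatom_site = "anterior torso", age = 0))
#' which(v == 1)  # positions 2, 3, 11
encode_record <- function(record, codebook = metadata_codebook()) {
  c(encode_sex(record$sex, codebook),
    encode_site(record$anatom_site, codebook),
    encode_age(record$age, codebook))
}

#' @rdname encode_record
#' @param vector binary vector of length 28.
#' @return `decode_vector`: list with `sex`, `anatom_site`, `age` (`NA` for
#'   an all-zero block).
#' @export
decode_vector <- function(vector, codebook = metadata_codebook()) {
  if (length(vector) != sum(codebook$dims))
    stop("vector must have length ", sum(codebook$dims))
  take <- function(block, categories) {
    ones <- which(block == 1)
    if (length(ones) == 0) return(NA)
    if (length(ones) > 1) stop("block has more than one set bit")
    categories[ones]
  }
  ends <- cumsum(codebook$dims)
  starts <- ends - codebook$dims + 1L
  list(sex = take(vector[starts[1]:ends[1]], codebook$sex),
       anatom_site = take(vector[starts[2]:ends[2]], codebook$anatom_site),
       age = take(vector[starts[3]:ends[3]], codebook$age))
}

#' Encode a metadata table
#'
#' @param metadata data.frame with columns `sex`, `anatom_site`, `age`.
#' @param codebook a [metadata_codebook()].
#' @return n x 28 binary matrix, one encoded record per row.
#' @export
encode_metadata_table <- function(metadata, codebook = metadata_codebook()) {
  need <- c("sex", "anatom_site", "age")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns sex, anatom_site, age")
  out <- matrix(0, nrow(metadata), sum(codebook$dims))
  for (i in seq_len(nrow(metadata)))
    out[i, ] <- encode_record(metadata[i, ], codebook)
  out
}

#' Serialise / load a codebook as JSON
#'
#' Round-tripping the codebook through JSON preserves every encoding
#' bit-exactly.
#'
#' @param codebook a [metadata_codebook()].
#' @param path JSON file path.
#' @return `write_codebook`: `path` invisibly; `read_codebook`: the codebook.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(unclass(codebook)[c("sex", "anatom_site", "age")],
                       path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sex = raw$sex, anatom_site = raw$anatom_site,
                 age = as.integer(raw$age),
                 dims = c(sex = length(raw$sex),
                          anatom_site = length(raw$anatom_site),
                          age = length(raw$age))),
            class = "metadata_codebook")
}
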