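# Internal key helpers: markers, extremities, regions, localizations.
# Identifiers must not contain the reserved separators ":", "~", "@", "--".

RESERVED_ID_CHARS <- c(":", "~", "@", " ")

check_ids <- function(ids, what = "identifier") {
  bad <- grepl("[:~@[:space:]]", ids)
  if (any(bad)) {
    stop(sprintf("%s contains reserved characters (':', '~', '@', whitespace): %s",
                 what, paste(utils::head(unique(ids[bad]), 3), collapse = ", ")))
  }
  invisible(ids)
}

marker_key <- function(id, side) paste0(id, ":", side)

marker_id <- function(key) sub(":[ht]$", "", key)

marker_side <- function(key) sub("^.*:([ht])$", "\\1", key)

other_side <- function(side) ifelse(side == "h", "t", "h")

# Canonical unordered-pair key for adjacencies / regions
pair_key <- function(a, b, sep = "--") {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = sep)
}

region_key <- function(e1, e2) pair_key(e1, e2, sep = "~")

region_extremities <- function(rkey) strsplit(rkey, "~", fixed = TRUE)

loc_key <- function(family, k) paste0(family, "@", k)

loc_family <- function(lkey) sub("@[0-9]+$", "", lkey)

`%||%` <- function(a, b) if (is.null(a)) b else a
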