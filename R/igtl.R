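# Minimal binary message protocol for image-guided-therapy links
# (version-1 header subset: TRANSFORM for calibration transfer, POINT
# for entry/target transfer). Wire format: 58-byte header
#   uint16  version (big-endian)
#   char12  type name (null-padded)
#   char20  device name (null-padded)
#   uint64  timestamp
#   uint64  body size
#   uint64  CRC-64/ECMA of the body
# followed by the body. All multi-byte integers big-endian. The
# TRANSFORM body is 12 big-endian float32: the three rotation columns
# then the translation. The POINT body is N x 3 big-endian float32
# (a deliberately reduced point record).

IGTL_HEADER_BYTES <- 58L

uint_to_be <- function(x, nbytes) {
  out <- raw(nbytes)
  x <- as.numeric(x)
  for (i in nbytes:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

be_to_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^((length(bytes) - 1):0))
}

padded_name <- function(name, width, what) {
  b <- charToRaw(name)
  cbct_check(length(b) <= width, "cbctnav_validation",
             sprintf("%s must be at most %d bytes", what, width))
  c(b, raw(width - length(b)))
}

name_from_raw <- function(bytes) {
  n <- which(bytes == as.raw(0))
  rawToChar(if (length(n)) bytes[seq_len(min(n) - 1)] else bytes)
}

encode_floats_be <- function(x) {
  writeBin(as.numeric(x), raw(), size = 4L, endian = "big")
}

decode_floats_be <- function(bytes) {
  readBin(bytes, "numeric", n = length(bytes) %/% 4L, size = 4L, endian = "big")
}

igtl_header <- function(type_name, device_name, timestamp, body) {
  c(uint_to_be(1, 2),                      # protocol version 1
    padded_name(type_name, 12, "type_name"),
    padded_name(device_name, 20, "device_name"),
    uint_to_be(timestamp, 8),
    uint_to_be(length(body), 8),
    crc64(body))
}

parse_header <- function(bytes) {
  if (length(bytes) < IGTL_HEADER_BYTES)
    cbct_abort("cbctnav_truncated", sprintf(
      "message truncated: %d bytes, need at least the %d-byte header",
      length(bytes), IGTL_HEADER_BYTES))
  list(version = be_to_uint(bytes[1:2]),
       type_name = name_from_raw(bytes[3:14]),
       device_name = name_from_raw(bytes[15:34]),
       timestamp = be_to_uint(bytes[35:42]),
       body_size = be_to_uint(bytes[43:50]),
       crc = bytes[51:58])
}

check_body <- function(hdr, bytes) {
  body <- bytes[-seq_len(IGTL_HEADER_BYTES)]
  if (length(body) != hdr$body_size)
    cbct_abort("cbctnav_truncated", sprintf(
      "body size mismatch: header says %d bytes, message carries %d",
      hdr$body_size, length(body)))
  if (!identical(crc64(body), hdr$crc))
    cbct_abort("cbctnav_crc_mismatch", "body CRC-64 does not match the header")
  body
}

#' Encode a rigid transform as a TRANSFORM message
#'
#' @param transform a [rigid_transform()].
#' @param device_name device string, at most 20 bytes.
#' @param timestamp integer-valued timestamp (seconds or ticks; stored
#'   verbatim as uint64).
#' @return Raw vector: 58-byte header + 48-byte body.
#' @export
encode_transform_message <- function(transform, device_name = "calibration",
                                     timestamp = 0) {
  cbct_check(is_rigid_transform(transform), "cbctnav_validation",
             "transform must be a rigid_transform (non-rigid input refused)")
  body <- encode_floats_be(c(transform$rotation[, 1], transform$rotation[, 2],
                             transform$rotation[, 3], transform$translation))
  c(igtl_header("TRANSFORM", device_name, timestamp, body), body)
}

#' Decode a TRANSFORM message
#'
#' Validates the CRC and body size before parsing. The float32 wire
#' rotation is re-projected (SVD) to the nearest exact rotation so the
#' returned object satisfies the rigid-transform invariants.
#'
#' @param bytes raw vector from [encode_transform_message()].
#' @return `list(transform = <rigid_transform>, device_name, timestamp,
#'   version)`.
#' @section Errors: `cbctnav_truncated`, `cbctnav_crc_mismatch`,
#'   `cbctnav_unknown_type`.
#' @export
decode_transform_message <- function(bytes) {
  hdr <- parse_header(bytes)
  if (hdr$type_name != "TRANSFORM")
    cbct_abort("cbctnav_unknown_type",
               sprintf("expected a TRANSFORM message, got '%s'", hdr$type_name))
  body <- check_body(hdr, bytes)
  v <- decode_floats_be(body)
  rot <- matrix(v[1:9], 3, 3)
  dec <- svd(rot)
  rot <- dec$u %*% diag(c(1, 1, sign(det(dec$u %*% t(dec$v))))) %*% t(dec$v)
  list(transform = rigid_transform(rot, v[10:12]),
       device_name = hdr$device_name, timestamp = hdr$timestamp,
       version = hdr$version)
}

#' Encode points as a POINT message
#'
#' @param points n x 3 matrix or 3-vector, mm.
#' @param device_name device string, at most 20 bytes.
#' @param timestamp as in [encode_transform_message()].
#' @return Raw vector.
#' @export
encode_point_message <- function(points, device_name = "target",
                                 timestamp = 0) {
  pts <- if (is.null(dim(points))) matrix(as_point3(points), 1)
         else as_points_matrix(points)
  body <- encode_floats_be(as.vector(t(pts)))
  c(igtl_header("POINT", device_name, timestamp, body), body)
}

#' Decode a POINT message
#'
#' @param bytes raw vector from [encode_point_message()].
#' @return `list(points = <n x 3 matrix>, device_name, timestamp,
#'   version)`.
#' @section Errors: `cbctnav_truncated`, `cbctnav_crc_mismatch`,
#'   `cbctnav_unknown_type`.
#' @export
decode_point_message <- function(bytes) {
  hdr <- parse_header(bytes)
  if (hdr$type_name != "POINT")
    cbct_abort("cbctnav_unknown_type",
               sprintf("expected a POINT message, got '%s'", hdr$type_name))
  body <- check_body(hdr, bytes)
  v <- decode_floats_be(body)
  list(points = matrix(v, ncol = 3, byrow = TRUE),
       device_name = hdr$device_name, timestamp = hdr$timestamp,
       version = hdr$version)
}
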