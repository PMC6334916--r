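# Unit-quaternion helpers for orientation math. Quaternions are stored as
# length-4 numeric vectors c(w, x, y, z) or n x 4 matrices; q maps device-frame
# vectors to the world frame via v_w = q (x) v_d (x) q*.

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation of angle theta (rad) about unit axis
quat_from_axis_angle <- function(axis, theta) {
  s <- sin(theta / 2)
  c(cos(theta / 2), axis[1] * s, axis[2] * s, axis[3] * s)
}

# minimal rotation taking unit vector `from` onto unit vector `to`
quat_between <- function(from, to) {
  d <- sum(from * to)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 deg: any axis orthogonal to `from`
    axis <- c(-from[2], from[1], 0)
    if (sum(axis^2) < 1e-12) axis <- c(0, -from[3], from[2])
    return(quat_from_axis_angle(axis / sqrt(sum(axis^2)), pi))
  }
  axis <- c(from[2] * to[3] - from[3] * to[2],
            from[3] * to[1] - from[1] * to[3],
            from[1] * to[2] - from[2] * to[1])
  quat_from_axis_angle(axis / sqrt(sum(axis^2)), acos(d))
}

# rotate a single 3-vector by quaternion q
quat_rotate <- function(q, v) {
  qv <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  qv[2:4]
}

# rotate an n x 3 matrix of vectors by an n x 4 matrix of quaternions
# (vectorized expansion of the sandwich product)
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  vx <- V[, 1]; vy <- V[, 2]; vz <- V[, 3]
  # t = 2 * q_vec x v
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + (y * tz - z * ty),
        vy + w * ty + (z * tx - x * tz),
        vz + w * tz + (x * ty - y * tx))
}
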