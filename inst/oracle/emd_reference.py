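#!/usr/bin/env python
"""Independent reference empirical mode decomposition.

Classic Huang sifting on numpy/scipy, used by the package's test-suite as an
independent cross-check of the R implementation. Reads a CSV whose columns
are signals, writes a CSV with the first intrinsic mode function of each
column.

Usage: python emd_reference.py in.csv out.csv
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline
from scipy.signal import argrelextrema


def extrema(x):
    mx = argrelextrema(x, np.greater_equal)[0]
    mn = argrelextrema(x, np.less_equal)[0]
    # drop plateaus duplicated by the >= / <= comparators
    mx = mx[(mx > 0) & (mx < len(x) - 1)]
    mn = mn[(mn > 0) & (mn < len(x) - 1)]
    mx = mx[np.diff(np.concatenate(([-(10)], mx))) > 1]
    mn = mn[np.diff(np.concatenate(([-(10)], mn))) > 1]
    return mx, mn


def envelope_mean(x):
    n = len(x)
    mx, mn = extrema(x)
    if len(mx) < 1 or len(mn) < 1:
        return None
    # mirror the two extrema nearest each boundary
    def extend(idx, vals):
        take = idx[: min(2, len(idx))]
        left = -take[::-1]
        taker = idx[-min(2, len(idx)):]
        right = 2 * (n - 1) - taker[::-1]
        xi = np.concatenate((left, idx, right))
        yi = np.concatenate((vals[take][::-1], vals[idx], vals[taker][::-1]))
        order = np.argsort(xi)
        xi, yi = xi[order], yi[order]
        keep = np.concatenate(([True], np.diff(xi) > 0))
        return xi[keep], yi[keep]

    t = np.arange(n)
    xu, yu = extend(mx, x)
    xl, yl = extend(mn, x)
    upper = CubicSpline(xu, yu, bc_type="natural")(t)
    lower = CubicSpline(xl, yl, bc_type="natural")(t)
    return (upper + lower) / 2.0


def sift(x, sd_threshold=0.2, max_iter=100):
    h = x.copy()
    for _ in range(max_iter):
        m = envelope_mean(h)
        if m is None:
            break
        sd = np.sum(m ** 2) / np.sum(h ** 2)
        h = h - m
        if sd < sd_threshold:
            break
    return h


def imf1(x):
    return sift(np.asarray(x, dtype=float))


def main():
    data = np.loadtxt(sys.argv[1], delimiter=",", ndmin=2)
    out = np.column_stack([imf1(data[:, j]) for j in range(data.shape[1])])
    np.savetxt(sys.argv[2], out, delimiter=",")


if __name__ == "__main__":
    main()
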