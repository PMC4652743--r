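/* Hartigan's dip statistic.
 *
 * dip(x) = min over unimodal CDFs U of sup |F_n - U|, computed by the
 * iterative greatest-convex-minorant / least-concave-majorant algorithm:
 * within the current candidate modal interval [low, high] the GCM and LCM
 * of the empirical CDF are fitted, the largest discrepancy between the two
 * fits locates the next (tighter) modal interval, and the deviations of
 * F_n from the fits outside it drive the dip value.  All distances are
 * kept in count units (F_n jumps by 1) and scaled by 1/(2n) at the end.
 */
#include <R.h>
#include <Rinternals.h>

SEXP C_dipstat(SEXP x_)
{
    const int n = LENGTH(x_);
    SEXP out = PROTECT(allocVector(REALSXP, 3)); /* dip, modal lo, modal hi */
    double *res = REAL(out);
    const double *xr = REAL(x_);

    if (n < 1) {
        res[0] = NA_REAL; res[1] = NA_REAL; res[2] = NA_REAL;
        UNPROTECT(1); return out;
    }

    /* 1-based working copy */
    double *x = (double *) R_alloc((size_t) n + 1, sizeof(double));
    for (int i = 1; i <= n; i++) x[i] = xr[i - 1];
    for (int i = 2; i <= n; i++)
        if (x[i] < x[i - 1]) error("'x' must be sorted increasingly");

    res[1] = x[1]; res[2] = x[n];
    if (n < 2 || x[n] == x[1]) { /* degenerate: a point mass is unimodal */
        res[0] = 0.0;
        UNPROTECT(1); return out;
    }

    int *mn  = (int *) R_alloc((size_t) n + 2, sizeof(int));
    int *mj  = (int *) R_alloc((size_t) n + 2, sizeof(int));
    int *gcm = (int *) R_alloc((size_t) n + 2, sizeof(int));
    int *lcm = (int *) R_alloc((size_t) n + 2, sizeof(int));

    int low = 1, high = n;
    double dip = 1.0;           /* count units; final minimum is 1/(2n) */

    for (;;) {
        /* GCM predecessor pointers on [low, high]; slope tests use cross
         * products so tied x values need no special casing here. */
        mn[low] = low;
        for (int j = low + 1; j <= high; j++) {
            mn[j] = j - 1;
            for (;;) {
                int mnj = mn[j], mnmnj = mn[mnj];
                if (mnj == low ||
                    (x[j] - x[mnj]) * (mnj - mnmnj) <
                    (x[mnj] - x[mnmnj]) * (j - mnj))
                    break;
                mn[j] = mnmnj;
            }
        }
        /* LCM successor pointers on [low, high] */
        mj[high] = high;
        for (int k = high - 1; k >= low; k--) {
            mj[k] = k + 1;
            for (;;) {
                int mjk = mj[k], mjmjk = mj[mjk];
                if (mjk == high ||
                    (x[k] - x[mjk]) * (mjk - mjmjk) <
                    (x[mjk] - x[mjmjk]) * (k - mjk))
                    break;
                mj[k] = mjmjk;
            }
        }

        /* touch points: gcm[] decreasing from high, lcm[] increasing from low */
        int l_gcm, l_lcm;
        gcm[1] = high;
        for (l_gcm = 1; gcm[l_gcm] > low; l_gcm++) gcm[l_gcm + 1] = mn[gcm[l_gcm]];
        lcm[1] = low;
        for (l_lcm = 1; lcm[l_lcm] < high; l_lcm++) lcm[l_lcm + 1] = mj[lcm[l_lcm]];

        /* largest discrepancy between the GCM and LCM fits */
        double d = 0.0;
        int ig = l_gcm, ih = l_lcm;
        if (l_gcm != 2 || l_lcm != 2) {
            int ix = l_gcm - 1, iv = 2;
            do {
                int gcmix = gcm[ix], lcmiv = lcm[iv];
                double dd, chord;
                if (gcmix > lcmiv) {
                    /* next touch (upwards) is the LCM's: gap at lcmiv vs the
                     * GCM chord gcm[ix+1] -> gcm[ix] */
                    int gcmi1 = gcm[ix + 1];
                    if (x[gcmix] > x[gcmi1])
                        chord = gcmi1 + (x[lcmiv] - x[gcmi1]) *
                            (gcmix - gcmi1) / (x[gcmix] - x[gcmi1]);
                    else
                        chord = gcmix;   /* vertical chord: top corner */
                    dd = (lcmiv + 1) - chord;
                    ++iv;
                    if (dd >= d) { d = dd; ig = ix + 1; ih = iv - 1; }
                } else {
                    /* next touch is the GCM's: gap at gcmix vs the LCM chord
                     * lcm[iv-1] -> lcm[iv] */
                    int lcmiv1 = lcm[iv - 1];
                    if (x[lcmiv] > x[lcmiv1])
                        chord = lcmiv1 + (x[gcmix] - x[lcmiv1]) *
                            (lcmiv - lcmiv1) / (x[lcmiv] - x[lcmiv1]);
                    else
                        chord = lcmiv;
                    dd = chord - (gcmix - 1);
                    --ix;
                    if (dd >= d) { d = dd; ig = ix + 1; ih = iv; }
                }
                if (ix < 1) ix = 1;
                if (iv > l_lcm) iv = l_lcm;
            } while (gcm[ix] != lcm[iv]);
        } else {
            d = 1.0;
        }
        if (d < dip) break;

        /* deviation of F_n above the GCM on [low, gcm[ig]] */
        double dl = 0.0;
        for (int j = ig; j < l_gcm; j++) {
            int je = gcm[j], jb = gcm[j + 1];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jr = jb; jr <= je; jr++) {
                    double t = (jr - jb + 1) - (x[jr] - x[jb]) * C;
                    if (t > dl) dl = t;
                }
            }
        }
        /* deviation of F_n below the LCM on [lcm[ih], high] */
        double du = 0.0;
        for (int j = ih; j < l_lcm; j++) {
            int jb = lcm[j], je = lcm[j + 1];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jr = jb; jr <= je; jr++) {
                    double t = (x[jr] - x[jb]) * C - (jr - jb - 1);
                    if (t > du) du = t;
                }
            }
        }
        double dm = (dl > du) ? dl : du;
        if (dm > dip) dip = dm;

        if (low == gcm[ig] && high == lcm[ih]) break; /* no progress */
        low = gcm[ig];
        high = lcm[ih];
    }

    res[0] = dip / (2.0 * n);
    res[1] = x[low];
    res[2] = x[high];
    UNPROTECT(1);
    return out;
}
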