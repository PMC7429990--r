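"""Monte-Carlo random-walk reference for restricted diffusion in a sphere.

Generates the frozen fixture tests/testthat/fixtures/sphere-mc-oracle.csv:
attenuation of a PGSE experiment (delta = 1 ms, Delta = 30 ms,
b = 5 ms/um^2, gradient along z) for spheres of radius r with intra-sphere
diffusivity D. Walkers start uniformly in the sphere, take Gaussian steps
with specular (radial mirror) reflection at the wall, and accumulate phase
phi = int gamma g(t) z(t) dt; the magnitude attenuation is E = <cos phi>.

Run once from the repository root:  python tools/mc_sphere_oracle.py
(takes ~45 min on one CPU; the CSV it writes is the frozen test fixture).
"""

import numpy as np
from numba import njit

GAMMA = 267.513e-6  # rad / (ms um) per mT/m
DELTA_SMALL = 1.0   # pulse duration, ms
DELTA_BIG = 30.0    # onset separation, ms
B_VALUE = 5.0       # ms/um^2
Q = np.sqrt(B_VALUE / (DELTA_BIG - DELTA_SMALL / 3.0))  # rad/um
G_AMP = Q / (GAMMA * DELTA_SMALL)  # mT/m (idealised)
N_WALKERS = 30_000
SEED = 20200415


@njit(fastmath=True)
def simulate(radius, diff, dt, n_walkers, seed):
    t_total = DELTA_BIG + DELTA_SMALL
    n_steps = int(np.ceil(t_total / dt))
    sig = np.sqrt(2.0 * diff * dt)
    gq = GAMMA * G_AMP
    np.random.seed(seed)
    acc = 0.0
    acc2 = 0.0
    for _ in range(n_walkers):
        x = 0.0
        y = 0.0
        z = 0.0
        while True:
            x = (np.random.rand() * 2.0 - 1.0) * radius
            y = (np.random.rand() * 2.0 - 1.0) * radius
            z = (np.random.rand() * 2.0 - 1.0) * radius
            if x * x + y * y + z * z <= radius * radius:
                break
        phi = 0.0
        for i in range(n_steps):
            t = i * dt
            if t < DELTA_SMALL:
                phi += gq * z * dt
            elif DELTA_BIG <= t < DELTA_BIG + DELTA_SMALL:
                phi -= gq * z * dt
            x += sig * np.random.randn()
            y += sig * np.random.randn()
            z += sig * np.random.randn()
            rr = np.sqrt(x * x + y * y + z * z)
            if rr > radius:
                s = (2.0 * radius - rr) / rr
                x *= s
                y *= s
                z *= s
        c = np.cos(phi)
        acc += c
        acc2 += c * c
    mean = acc / n_walkers
    var = acc2 / n_walkers - mean * mean
    return mean, np.sqrt(var / n_walkers)


def main():
    rows = []
    for radius in (2.0, 5.0, 10.0):
        for diff in (1.0, 3.0):
            # rms 3D step 0.05 um where the wall curvature is tight or the
            # example case demands it, 0.1 um otherwise
            step = 0.05 if (radius <= 2.0 or diff == 3.0 and radius == 5.0) else 0.1
            dt = step ** 2 / (6.0 * diff)
            e, se = simulate(radius, diff, dt, N_WALKERS, SEED)
            rows.append((radius, diff, e, se))
            print(f"r={radius} D={diff} dt={dt:.2e} E={e:.5f} se={se:.5f}", flush=True)
    with open("tests/testthat/fixtures/sphere-mc-oracle.csv", "w") as fh:
        fh.write("# Synthetic Monte-Carlo reference (random walk, reflecting sphere)\n")
        fh.write("# PGSE delta=1 ms, Delta=30 ms, b=5 ms/um^2, gradient along z\n")
        fh.write(f"# {N_WALKERS} walkers, rms step <= 0.1 um (0.05 at r=2 and r=5,D=3), seed {SEED}\n")
        fh.write("# generated once by tools/mc_sphere_oracle.py\n")
        fh.write("r_um,D_um2_ms,attenuation_mc,se_mc\n")
        for r, d, e, se in rows:
            fh.write(f"{r},{d},{e:.6f},{se:.6f}\n")


if __name__ == "__main__":
    main()
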