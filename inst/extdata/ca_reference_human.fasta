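>ca_human author_start=108 curated human TCR alpha constant (Ca) Ig-domain reference
PNIQNPDPAVYQLRDSKSSDKSVCLFTDFDSQTNVSQSKDSDVYITDKTVLDMRSMDFKSNSAVAWSNKSDFACANAFNNSIIPEDTFFPSPESS
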