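>Q99524 Sigma non-opioid intracellular receptor 1, Homo sapiens (SIGMAR1)
MQWAVGRRWAWAALLLAVAAVLTQVVWLWLGTQSFVFQREEIAQLARQYAGLDHELAFSR
LIVELRRLHPGHVLPDEELQWVFVNAGGWMGAMCLLHASLSEYVLLFGTALGSRGHSGRY
WAEISDTIISGTFHQWREGTTKSEVFYPGETVVHGPGEATAVEWGPNTWMVEYGRGVIPS
TLAFALADTVFSTQDFLTLFYTLRSYARGLRLELTTYLFGQDP
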