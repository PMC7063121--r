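# General DPF equation coefficients, Scholkmann & Wolf (2013),
# J Biomed Opt 18(10):105004: DPF = alpha + beta*Age^gamma
#   + delta*lambda^3 + epsilon*lambda^2 + zeta*lambda
term,value
alpha,223.3
beta,0.05624
gamma,0.8493
delta,-5.723e-7
epsilon,0.001245
zeta,-0.9025
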