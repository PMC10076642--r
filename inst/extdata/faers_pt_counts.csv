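drug,group,pt,n_events
secukinumab,IBD,Crohn's disease,233
secukinumab,IBD,Colitis ulcerative,196
secukinumab,IBD,Inflammatory bowel disease,182
ixekizumab,IBD,Crohn's disease,43
ixekizumab,IBD,Colitis ulcerative,67
ixekizumab,IBD,Inflammatory bowel disease,50
brodalumab,IBD,Crohn's disease,1
brodalumab,IBD,Colitis ulcerative,2
brodalumab,IBD,Inflammatory bowel disease,0
secukinumab,colitis,Colitis,223
secukinumab,colitis,Microscopic colitis,28
secukinumab,colitis,Ischaemic colitis,10
secukinumab,colitis,Proctitis,10
secukinumab,colitis,Proctitis ulcerative,4
secukinumab,colitis,Proctitis haemorrhagic,0
secukinumab,colitis,Enteritis,22
secukinumab,colitis,Enterocolitis,10
secukinumab,colitis,Enterocolitis haemorrhagic,5
secukinumab,colitis,Eosinophilic colitis,1
secukinumab,colitis,Colitis erosive,1
ixekizumab,colitis,Colitis,53
ixekizumab,colitis,Microscopic colitis,8
ixekizumab,colitis,Ischaemic colitis,2
ixekizumab,colitis,Proctitis,0
ixekizumab,colitis,Proctitis ulcerative,0
ixekizumab,colitis,Proctitis haemorrhagic,1
ixekizumab,colitis,Enteritis,2
ixekizumab,colitis,Enterocolitis,1
ixekizumab,colitis,Enterocolitis haemorrhagic,4
ixekizumab,colitis,Eosinophilic colitis,1
ixekizumab,colitis,Colitis erosive,1
brodalumab,colitis,Colitis,3
brodalumab,colitis,Microscopic colitis,0
brodalumab,colitis,Ischaemic colitis,0
brodalumab,colitis,Proctitis,0
brodalumab,colitis,Proctitis ulcerative,0
brodalumab,colitis,Proctitis haemorrhagic,0
brodalumab,colitis,Enteritis,0
brodalumab,colitis,Enterocolitis,0
brodalumab,colitis,Enterocolitis haemorrhagic,0
brodalumab,colitis,Eosinophilic colitis,0
brodalumab,colitis,Colitis erosive,0
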