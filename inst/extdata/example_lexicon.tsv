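# surface	drug_class	is_noise	variants
oxycodone	prescription	false	oxycdone,oxycodne,oxycodon
oxycontin	prescription	false	oxycntin,oxycontn,oxyocntin
percocet	prescription	false	prcocet,perccet,percoct
vicodin	prescription	false	vcodin,vicdin,vicodn
hydrocodone	prescription	false	hydrcodone,hydrocdone,hydrocodne
codeine	prescription	false	cdeine,codine,codene
tramadol	prescription	false	trmadol,tramdol,tramadl
morphine	prescription	false	mrphine,morphne,morphin
methadone	prescription	false	mthadone,methdone,methadne
suboxone	prescription	false	sboxone,subxone,suboxne
fentanyl	prescription	false	fntanyl,fentnyl,fnetanyl
dilaudid	prescription	false	dlaudid,diludid,diladid
opana	prescription	false	opna,opan,oapna
roxicodone	prescription	false	rxicodone,roxcodone,roxicdone
heroin	illicit	false	hroin,herin,heron
china white	illicit	false	chna white,chin white,cihna white
oxys	illicit	false	ooxys,oys,oxs
percs	illicit	false	prcs,precs,peercs
speedball	illicit	false	spedball,speedbll,sepedball
dope	illicit	true	dpe,dop,dpoe
tar	illicit	true	tr,tra,taar
skunk	illicit	true	sknk,suknk,sknuk
smack	illicit	true	smck,samck,smcak
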